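test_that("polarity classification follows the excitation/inhibition rule", {
  # cohort-typical pre-operative values: excitatory out of the SOZ,
  # inhibitory back toward it
  fw <- connection_estimate("HH", "pZ", 0.21, 0.99, "pre")
  bw <- connection_estimate("pZ", "HH", -1.18, 0.99, "pre")
  call <- classify_direction(fw, bw, 0.9)
  expect_identical(call$soz, "HH")
  expect_identical(call$pz, "pZ")
  expect_identical(call$status, "expected")
  # nothing significant: indeterminate, no call
  ns <- classify_direction(connection_estimate("A", "B", 0.4, 0.5),
                           connection_estimate("B", "A", -0.4, 0.5))
  expect_identical(ns$status, "indeterminate")
  expect_true(is.na(ns$soz))
  # flipped polarity: the second node is called SOZ, flagged reversed
  rv <- classify_direction(connection_estimate("A", "B", -0.3, 0.95),
                           connection_estimate("B", "A", 0.2, 0.95))
  expect_identical(rv$soz, "B")
  expect_identical(rv$status, "reversed")
  # conflicting significant votes: indeterminate
  cf <- classify_direction(connection_estimate("A", "B", 0.3, 0.95),
                           connection_estimate("B", "A", 0.3, 0.95))
  expect_identical(cf$status, "indeterminate")
})

test_that("classification is antisymmetric under node relabelling", {
  fw <- connection_estimate("A", "B", 0.3, 0.95)
  bw <- connection_estimate("B", "A", -0.5, 0.95)
  c1 <- classify_direction(fw, bw)
  c2 <- classify_direction(bw, fw)     # presumed SOZ is now B
  expect_identical(c1$soz, c2$soz)     # the call follows the node
  expect_identical(c1$status, "expected")
  expect_identical(c2$status, "reversed")
})

test_that("self-connections and mismatched pairs are rejected", {
  expect_error(classify_direction(
    connection_estimate("A", "A", 0.1, 0.9),
    connection_estimate("A", "B", 0.1, 0.9)), "self-connection")
  expect_error(classify_direction(
    connection_estimate("A", "B", 0.1, 0.9),
    connection_estimate("C", "A", 0.1, 0.9)), "same pair")
})

test_that("the recovery index is the proportional reduction in percent", {
  expect_identical(round_half_up(recovery_index(0.28, 0.08)), 71)
  expect_identical(round_half_up(recovery_index(-0.91, 0.47)), 152)
  expect_identical(recovery_index(0.5, 0.5), 0)
  expect_identical(recovery_index(0.5, 0), 100)
  # scale-free: common positive rescaling changes nothing
  expect_equal(recovery_index(0.28, 0.08),
               recovery_index(2.8, 0.8))
  expect_error(recovery_index(0, 0.1), "undefined")
  expect_error(recovery_index(1e-9, 0.1), "undefined")
})

test_that("recovery records derive flags consistently from values", {
  r <- recovery_record("s", 0.28, 0.08, -0.97, -0.26)
  expect_true(r$reduced_excitation); expect_false(r$became_inhibitory)
  expect_true(r$reduced_inhibition); expect_false(r$became_excitatory)
  expect_identical(r$soz_recovery_index, 71)
  expect_identical(r$pz_recovery_index, 73)
  expect_identical(r$bni, 144)
  r2 <- recovery_record("t", 0.5, -0.52, -0.91, 0.47)
  expect_true(r2$became_inhibitory)
  expect_true(r2$became_excitatory)
  expect_error(recovery_record("u", 0.1, NA, -0.5, -0.2), "required")
})

test_that("the BNI sums the indices and applies the 70% threshold", {
  expect_identical(compute_bni(list(soz_recovery_index = 71,
                                    pz_recovery_index = 73))$bni, 144)
  expect_true(compute_bni(list(soz_recovery_index = 71,
                               pz_recovery_index = 73))$sub_seizure_threshold)
  b <- compute_bni(list(soz_recovery_index = -621,
                        pz_recovery_index = -359))
  expect_identical(b$bni, -980)
  expect_false(b$sub_seizure_threshold)
  z <- compute_bni(list(soz_recovery_index = 0, pz_recovery_index = 0))
  expect_identical(z$bni, 0)
  expect_false(z$sub_seizure_threshold)
  # obliterated records: undefined BNI but predicted sub-threshold
  ob <- compute_bni(recovery_record("x", obliterated = TRUE))
  expect_true(is.na(ob$bni))
  expect_true(ob$sub_seizure_threshold)
  expect_error(compute_bni(list(soz_recovery_index = 10)), "missing")
})

test_that("record summaries use the sample standard deviation", {
  recs <- lapply(1:4, function(i)
    list(soz_recovery_index = 50, pz_recovery_index = 50, bni = 100))
  s <- summarize_records(recs)
  expect_true(all(s$sd == 0))
  expect_true(all(s$mean == c(50, 50, 100)))
  expect_error(summarize_records(recs[1]), "at least 2")
})
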