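# Distogram integration, contact extraction, reference scanning, scoring,
# and the plausibility classifier.

test_that("contact_probability matches the brute-force bin oracle", {
  # all mass below the cutoff -> 1; straddling bin -> linear fraction
  dg <- new_distogram(array(rep(c(1, 0, 0), each = 4L), c(2L, 2L, 3L)),
                      c(4, 8))
  expect_true(all(contact_probability(dg, cutoff = 8) == 1))
  straddle <- new_distogram(array(rep(c(0, 1, 0), each = 4L), c(2L, 2L, 3L)),
                            c(7.5, 8.5))
  expect_true(all(contact_probability(straddle, cutoff = 8) == 0.5))
  expect_true(all(contact_probability(straddle, cutoff = 8,
                                      mode = "floor") == 0))
  # random normalized distograms vs the oracle, 1e-9
  withr::with_seed(31L, {
    for (rep in 1:25) {
      dg <- random_distogram(L = 3L, nb = sample(4:10, 1))
      cutoff <- runif(1, 3, 19)
      # random cutoffs may fall outside the random edge range; the
      # boundary warnings are themselves tested separately
      cp <- suppressWarnings(contact_probability(dg, cutoff))
      for (i in 1:3) for (j in 1:3)
        expect_equal(cp[i, j],
                     oracle_contact_prob(dg$probs[i, j, ], dg$bin_edges,
                                         cutoff),
                     tolerance = 1e-9)
      # monotone non-decreasing in cutoff
      cp2 <- suppressWarnings(contact_probability(dg, cutoff + runif(1, 0, 3)))
      expect_true(all(cp2 - cp >= -1e-12))
    }
  })
})

test_that("cutoff below the first interior edge uses the open bin only", {
  dg <- new_distogram(array(c(rep(0.25, 4L), rep(0.75, 4L)), c(2L, 2L, 2L)),
                      5)
  expect_warning(cp <- contact_probability(dg, cutoff = 3), "lower bin")
  expect_true(all(cp == 0.25))
})

test_that("reference_contacts equals an exhaustive scan with strict cutoff", {
  # 7.99 A in, 8.00 A out
  near <- micro_complex(dab = 7.99)
  exact <- micro_complex(dab = 8.00)
  kn <- contact_key_df(reference_contacts(near))
  expect_true("A|1|B|1" %in% kn)
  expect_false("A|1|B|1" %in% contact_key_df(reference_contacts(exact)))
  # generated complex vs naive double loop
  cx <- toy_complex(lengths = c(25L, 20L), seed = 41L)
  got <- reference_contacts(cx, cutoff = 8)
  naive <- character(0)
  for (i in seq_len(25)) for (j in seq_len(20)) {
    d <- sqrt(sum((cx$chains[["A"]]$cb[i, ] - cx$chains[["B"]]$cb[j, ])^2))
    if (d < 8) naive <- c(naive, paste("A", i, "B", j, sep = "|"))
  }
  expect_setequal(contact_key_df(got), naive)
  expect_warning(reference_contacts(new_complex(list(cx$chains[["A"]]))),
                 "single-chain")
})

test_that("predicted_contacts filters scope and threshold correctly", {
  truth <- toy_complex(lengths = c(30L, 28L), seed = 42L)
  targets <- vapply(truth$chains, `[[`, character(1), "sequence")
  merged <- merge_chains(targets)
  be <- mock_backend_from_truth(truth, noise_scale = 0)
  req <- prediction_request(merged, merge_msas(lapply(targets,
                                                      single_sequence_msa),
                                               merged),
                            NULL, model_ids = 1L, seed = 1L)
  res <- predict_models(req, be)[[1]]
  pred <- predicted_contacts(res, merged, threshold = 0.8, cutoff = 8)
  ref <- reference_contacts(truth, cutoff = 8)
  expect_identical(contact_key_df(pred), contact_key_df(ref))
  expect_true(all(pred$prob == 1))
  expect_true(all(pred$chain_a != pred$chain_b))  # intra-chain excluded
  # threshold 1.0 empties the set (strict inequality)
  expect_identical(nrow(predicted_contacts(res, merged, threshold = 1)), 0L)
  expect_error(predicted_contacts(res, merged, threshold = 0), "threshold")
})

test_that("score_contacts matches naive set arithmetic", {
  mk <- function(df) {
    df$aa_a <- "A"; df$aa_b <- "V"; df$prob <- NA_real_
    gapstitch:::new_contact_set(df)
  }
  withr::with_seed(43L, {
    for (rep in 1:20) {
      univ <- expand.grid(res_a = 1:10, res_b = 1:10)
      pick <- function(n) {
        k <- univ[sample(nrow(univ), n), ]
        data.frame(chain_a = "A", res_a = k$res_a,
                   chain_b = "B", res_b = k$res_b,
                   stringsAsFactors = FALSE)
      }
      p <- mk(pick(sample(0:50, 1)))
      r <- mk(pick(sample(1:50, 1)))
      t <- mk(pick(sample(1:50, 1)))
      m <- score_contacts(p, r, t)
      kp <- contact_key_df(p); kr <- contact_key_df(r)
      kt <- contact_key_df(t)
      tp <- sum(kp %in% kr)
      expect_identical(m$n_true_positive, as.integer(tp))
      if (nrow(p)) {
        expect_equal(m$precision, tp / nrow(p))
        expect_equal(m$template_satisfaction, sum(kp %in% kt) / nrow(p))
        expect_true(m$precision >= 0 && m$precision <= 1)
      } else {
        expect_true(is.na(m$precision))
        expect_true(is.na(m$template_satisfaction))
        expect_false(m$defined[["precision"]])
      }
      expect_equal(m$recall, tp / nrow(r))
      expect_lte(m$n_true_positive, min(m$n_predicted, m$n_reference))
    }
  })
})

test_that("identical non-empty sets give precision = recall = 1", {
  ref <- reference_contacts(toy_complex(seed = 44L))
  expect_gt(nrow(ref), 0L)
  m <- score_contacts(ref, ref)
  expect_identical(m$precision, 1)
  expect_identical(m$recall, 1)
})

test_that("chain-name mismatch between sets errors", {
  a <- reference_contacts(toy_complex(lengths = c(10L, 10L), seed = 45L,
                                      chain_ids = c("A", "B")))
  b <- reference_contacts(toy_complex(lengths = c(10L, 10L), seed = 45L,
                                      chain_ids = c("X", "Y")))
  expect_gt(nrow(a), 0L)
  expect_error(score_contacts(a, b), "chain names")
})

test_that("classify_plausible thresholds the contact count", {
  ref <- reference_contacts(micro_complex(dab = 6))  # 4 contacts
  take <- function(n) gapstitch:::new_contact_set(
    as.data.frame(ref)[seq_len(n), , drop = FALSE])
  expect_true(classify_plausible(take(3L), min_contacts = 3L))
  expect_false(classify_plausible(take(2L), min_contacts = 3L))
  expect_false(classify_plausible(take(0L), min_contacts = 1L))
  expect_error(classify_plausible(take(3L), min_contacts = 0L),
               "min_contacts")
})

test_that("interface counts aggregate per chain pair", {
  cx <- toy_complex(lengths = c(15L, 15L, 15L), seed = 46L)
  ref <- reference_contacts(cx)
  ic <- interface_counts(ref)
  expect_identical(sum(ic$n_contacts), nrow(ref))
  expect_true(all(ic$chain_a < ic$chain_b))
})
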