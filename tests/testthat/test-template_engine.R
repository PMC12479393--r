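# Template engine: alignment-based identity, greedy assignment, chain
# merging arithmetic, template feature projection, rigid-body perturbation.

test_that("sequence_identity matches the exhaustive alignment oracle", {
  expect_identical(sequence_identity("MKVL", "MKVL"), 1)
  expect_identical(sequence_identity("AAAA", "GGGG"), 0)
  # the spec's worked fragment case, expected value computed by the oracle
  o <- oracle_align("MKVLQ", "MKV")
  expect_equal(sequence_identity("MKVLQ", "MKV"), unname(o["identity"]))
  a <- align_global("MKVLQ", "MKV")
  expect_equal(a$score, unname(o["score"]))
  # random short strings, both orders (symmetry included)
  withr::with_seed(42L, {
    for (rep in 1:12) {
      x <- paste(sample(c("A", "G", "K", "V", "M"), sample(2:5, 1),
                        replace = TRUE), collapse = "")
      y <- paste(sample(c("A", "G", "K", "V", "M"), sample(2:5, 1),
                        replace = TRUE), collapse = "")
      o <- oracle_align(x, y)
      r <- align_global(x, y)
      expect_equal(r$score, unname(o["score"]), info = paste(x, y))
      expect_equal(r$identity, unname(o["identity"]), info = paste(x, y))
      expect_equal(sequence_identity(x, y), sequence_identity(y, x),
                   info = paste(x, y))
    }
  })
  expect_error(sequence_identity("", "MKV"), "non-empty")
})

test_that("align_global traceback pairs are a consistent global alignment", {
  withr::with_seed(7L, {
    letters20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
    for (rep in 1:10) {
      x <- paste(sample(letters20, sample(5:30, 1), replace = TRUE),
                 collapse = "")
      y <- paste(sample(letters20, sample(5:30, 1), replace = TRUE),
                 collapse = "")
      r <- align_global(x, y)
      p <- r$pairs
      if (nrow(p) > 1L) {
        expect_true(all(diff(p[, 1]) > 0) && all(diff(p[, 2]) > 0))
      }
      xs <- strsplit(x, "")[[1]]; ys <- strsplit(y, "")[[1]]
      expect_identical(sum(xs[p[, 1]] == ys[p[, 2]]), as.integer(r$matches))
    }
  })
})

test_that("assign_chains follows the greedy rule with deterministic ties", {
  # two identical targets, template with two identical chains:
  # target 1 takes the lexicographically first chain
  seqs <- rep("MKVLAGDEKW", 2L)
  tmpl <- new_complex(list(
    new_chain_record("B", "MKVLAGDEKW", 1:10, matrix(rnorm(30), 10)),
    new_chain_record("A", "MKVLAGDEKW", 1:10, matrix(rnorm(30), 10))))
  asg <- assign_chains(seqs, tmpl)
  expect_identical(asg$pairs$template_chain_id, c("A", "B"))
  expect_equal(asg$pairs$identity, c(1, 1))
  # one target, three chains, exactly one perfect match
  tmpl3 <- new_complex(list(
    new_chain_record("A", "GGGGGGGGGG", 1:10, matrix(rnorm(30), 10)),
    new_chain_record("B", "MKVLAGDEKW", 1:10, matrix(rnorm(30), 10)),
    new_chain_record("C", "PPPPPPPPPP", 1:10, matrix(rnorm(30), 10))))
  asg3 <- assign_chains("MKVLAGDEKW", tmpl3)
  expect_identical(asg3$pairs$template_chain_id, "B")
  expect_setequal(asg3$unmatched_template_chains, c("A", "C"))
  expect_length(asg3$unmatched_targets, 0L)
})

test_that("greedy_assign equals the independent oracle on random matrices", {
  withr::with_seed(11L, {
    agree_optimal <- 0L; n_cases <- 0L
    for (rep in 1:60) {
      nt <- sample(2:4, 1); nc <- sample(2:4, 1)
      m <- matrix(round(runif(nt * nc), 2), nt, nc,
                  dimnames = list(NULL, LETTERS[seq_len(nc)]))
      got <- greedy_assign(m)
      want <- oracle_greedy(m)
      expect_equal(got$pairs$target_index, want$target_index)
      expect_identical(got$pairs$template_chain_id, want$template_chain_id)
      expect_equal(got$pairs$identity, want$identity)
      # record (not assert) agreement with the optimal assignment
      n_cases <- n_cases + 1L
      if (abs(sum(got$pairs$identity) - oracle_optimal_total(m)) < 1e-12)
        agree_optimal <- agree_optimal + 1L
    }
    message(sprintf("greedy equals optimal assignment in %d/%d random cases",
                    agree_optimal, n_cases))
  })
})

test_that("merge_chains index arithmetic matches the stated layout", {
  m <- merge_chains(c(strrep("A", 60), strrep("G", 55)), gap_size = 200L)
  expect_identical(nchar(m$sequence), 115L)
  expect_identical(m$residue_index[1], 1L)
  expect_identical(m$residue_index[61], 261L)  # 60 + 200 + 1
  m3 <- merge_chains(rep(strrep("K", 10), 3L), gap_size = 5L)
  expect_identical(m3$residue_index[c(1L, 11L, 21L)], c(1L, 16L, 31L))
  single <- merge_chains(strrep("V", 40), gap_size = 200L)
  expect_identical(single$residue_index, 1:40)
  # boundary jumps are gap_size + 1 exactly, and 1 within chains
  jumps <- diff(m$residue_index)
  expect_identical(jumps[60], 201L)
  expect_true(all(jumps[-60] == 1L))
  expect_error(merge_chains(character(0)), "no target")
  expect_error(merge_chains("MKV", gap_size = 0L), "gap_size")
})

test_that("build_template_features maps template geometry onto merged positions", {
  truth <- toy_complex(lengths = c(30L, 25L), seed = 5L)
  targets <- vapply(truth$chains, `[[`, character(1), "sequence")
  merged <- merge_chains(targets)
  asg <- assign_chains(targets, truth)
  tf <- build_template_features(merged, asg, truth)
  # identity alignment: mask everywhere, coordinates equal template exactly
  expect_true(all(tf$mask))
  expect_identical(tf$cb[1:30, ], truth$chains[["A"]]$cb)
  expect_identical(tf$cb[31:55, ], truth$chains[["B"]]$cb)
  expect_identical(paste(tf$template_sequence, collapse = ""),
                   merged$sequence)
  # unassigned chain -> all-false mask over its block
  tmpl1 <- new_complex(list(truth$chains[["A"]]))
  asg1 <- assign_chains(targets, tmpl1)
  expect_identical(asg1$unmatched_targets, 2L)
  tf1 <- build_template_features(merged, asg1, tmpl1)
  expect_true(all(tf1$mask[1:30]))
  expect_false(any(tf1$mask[31:55]))
  expect_true(all(is.na(tf1$cb[31:55, ])))
})

test_that("template residues absent from the target map to no merged position", {
  # template chain has 5 extra N-terminal residues
  truth <- toy_complex(lengths = 30L, seed = 9L, chain_ids = "A")
  target <- truth$chains[["A"]]$sequence
  ext_seq <- paste0("XXXXX", target)  # X never occurs in toy sequences
  ext <- new_chain_record("A", ext_seq, 1:35,
                          ca = rbind(matrix(0, 5, 3) + 99,
                                     truth$chains[["A"]]$ca),
                          cb = rbind(matrix(0, 5, 3) + 99,
                                     truth$chains[["A"]]$cb))
  merged <- merge_chains(target)
  asg <- assign_chains(target, new_complex(list(ext)))
  tf <- build_template_features(merged, asg, new_complex(list(ext)))
  aln <- align_global(target, ext_seq)
  # oracle: the only optimal alignment maps target i -> template i + 5
  expect_identical(aln$pairs[, 2], aln$pairs[, 1] + 5L)
  expect_true(all(tf$mask))
  expect_equal(tf$cb, truth$chains[["A"]]$cb)
  expect_false(any(tf$cb == 99, na.rm = TRUE))
})

test_that("perturb_template is rigid, bounded and seed-reproducible", {
  cx <- toy_complex(lengths = c(25L, 20L), seed = 13L)
  # identity spec returns input coordinates
  id <- perturb_template(cx, max_angle = 0, max_shift = 0, seed = 4L)
  for (ch in names(cx$chains))
    expect_lt(max(abs(id$chains[[ch]]$cb - cx$chains[[ch]]$cb)), 1e-9)
  p1 <- perturb_template(cx, 30, 5, seed = 8L)
  p2 <- perturb_template(cx, 30, 5, seed = 8L)
  expect_identical(p1$chains[["A"]]$cb, p2$chains[["A"]]$cb)  # bit-identical
  p3 <- perturb_template(cx, 30, 5, seed = 9L)
  expect_gt(max(abs(p1$chains[["A"]]$cb - p3$chains[["A"]]$cb)), 1e-6)
  # rigidity: intra-chain pairwise distances preserved
  for (ch in names(cx$chains)) {
    d0 <- dist(rbind(cx$chains[[ch]]$ca, cx$chains[[ch]]$cb))
    d1 <- dist(rbind(p1$chains[[ch]]$ca, p1$chains[[ch]]$cb))
    expect_lt(max(abs(d0 - d1)), 1e-6)
  }
  # transform metadata matches the realized motion of the centroid
  tr <- attr(p1, "transforms")
  for (ch in names(cx$chains)) {
    expect_lte(tr[[ch]]$angle_deg, 30)
    expect_lte(tr[[ch]]$shift_mag, 5)
    moved <- colMeans(rbind(p1$chains[[ch]]$ca, p1$chains[[ch]]$cb))
    expect_equal(moved, cx$chains[[ch]]$com + tr[[ch]]$shift,
                 tolerance = 1e-9)
  }
  expect_error(perturb_template(cx, -1, 5), "non-negative")
})

test_that("chains move independently across the complex", {
  cx <- toy_complex(lengths = c(20L, 20L), seed = 1L)
  # chain A transform must not depend on whether chain B exists
  shifts <- vapply(1:40, function(s) {
    attr(perturb_template(cx, 30, 5, seed = s), "transforms")[["A"]]$shift_mag
  }, numeric(1))
  shiftsB <- vapply(1:40, function(s) {
    attr(perturb_template(cx, 30, 5, seed = s), "transforms")[["B"]]$shift_mag
  }, numeric(1))
  expect_lt(abs(cor(shifts, shiftsB)), 0.5)  # uncorrelated draws
})
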