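# Alignment handling, diversity subsampling and conservation scoring.

test_that("aligned FASTA round trips and malformed input is rejected", {
  p <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACD-EF", ">b", "ACDGEF", ">c", "ACEGEF"), p)
  m <- read_msa(p, ref_id = "a")
  expect_s3_class(m, "bd_msa")
  expect_equal(names(m), c("a", "b", "c"))
  expect_equal(unname(unclass(m)[1]), "ACD-EF")
  p2 <- withr::local_tempfile(fileext = ".fasta")
  write_msa(m, p2)
  m2 <- read_msa(p2)
  expect_equal(unclass(m2), unclass(m), ignore_attr = TRUE)
  # ragged rows
  p3 <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACDEF", ">bad", "ACD"), p3)
  expect_error(read_msa(p3), "bad")
  # duplicate ids
  p4 <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACDEF", ">a", "ACDEF"), p4)
  expect_error(read_msa(p4), "duplicate")
})

test_that("mismatch distances match hand counts and a brute-force recount", {
  m <- msa(c(a = "AAAAAAAAAA", b = "AAAAAAAAAA", c = "CCCAAAAAAA"))
  D <- pairwise_distance_matrix(m)
  expect_equal(D["a", "b"], 0)
  expect_equal(D["a", "c"], 0.3)
  expect_equal(diag(D), c(a = 0, b = 0, c = 0))
  expect_equal(D, t(D))
  gen <- make_msa(msa_spec(n_rows = 12, n_cols = 25, seed = 61))
  D2 <- pairwise_distance_matrix(gen$msa)
  M <- do.call(rbind, strsplit(unclass(gen$msa), ""))
  for (pair in list(c(1, 2), c(3, 9), c(5, 12))) {
    i <- pair[1]; j <- pair[2]
    comp <- M[i, ] != "-" & M[j, ] != "-"
    expect_equal(D2[i, j], mean(M[i, comp] != M[j, comp]))
  }
  expect_true(all(D2 >= 0 & D2 <= 1))
})

test_that("maxmin subsampling is deterministic and matches an independent oracle", {
  m3 <- msa(c(s1 = "AAAA", s2 = "AAAA", s3 = "CCCC"))
  sub <- maxmin_subsample(m3, 2)
  expect_setequal(names(sub), c("s1", "s3"))
  gen <- make_msa(msa_spec(n_rows = 8, n_cols = 30, random_rate = 0.5,
                           seed = 62))
  D <- pairwise_distance_matrix(gen$msa)
  sub4 <- maxmin_subsample(gen$msa, 4)
  expect_equal(match(names(sub4), names(gen$msa)), maxmin_oracle(D, 4))
  # n = rows returns the input
  expect_equal(unclass(maxmin_subsample(gen$msa, 8)), unclass(gen$msa),
               ignore_attr = TRUE)
})

test_that("maxmin selections dominate random subsets in minimum distance", {
  gen <- make_msa(msa_spec(n_rows = 30, n_cols = 40, random_rate = 0.4,
                           gap_rate = 0, seed = 63))
  D <- pairwise_distance_matrix(gen$msa)
  sel <- match(names(maxmin_subsample(gen$msa, 8)), names(gen$msa))
  min_of <- function(idx) min(D[idx, idx][upper.tri(diag(length(idx)))])
  ours <- min_of(sel)
  withr::with_seed(64, {
    wins <- mean(vapply(1:1000, function(i)
      ours >= min_of(sample(30, 8)), logical(1)))
  })
  expect_gte(wins, 0.99)
})

test_that("column JS divergence has the stated anchors and symmetry", {
  prm <- conservation_params(pseudocount = 0)
  bg <- prm$background
  # column distribution equal to the background scores 0
  counts <- round(bg * 10000)
  col_bg <- rep(names(bg), counts)
  expect_equal(js_divergence_column(col_bg, prm),
               0, tolerance = 1e-4)
  # invariant gap-free column equals the closed-form point-mass JSD
  col_inv <- rep("W", 50)
  expect_equal(js_divergence_column(col_inv, prm),
               jsd_point_mass("W", bg), tolerance = 1e-10)
  # permuted columns score identically
  col <- c(rep("A", 30), rep("S", 15), rep("-", 5))
  withr::with_seed(65, perm <- sample(col))
  expect_equal(js_divergence_column(col, conservation_params()),
               js_divergence_column(perm, conservation_params()))
  # bounded in [0, 1]
  withr::with_seed(66, {
    for (k in 1:20) {
      rnd <- sample(c(names(bg), "-"), 40, replace = TRUE)
      s <- js_divergence_column(rnd, conservation_params())
      expect_gte(s, 0); expect_lte(s, 1)
    }
  })
  # all-gap column scores 0 and is flagged
  sc <- js_divergence_column(rep("-", 10), prm)
  expect_equal(as.numeric(sc), 0)
  expect_true(attr(sc, "all_gap"))
})

test_that("gap fraction down-weights the column score multiplicatively", {
  prm <- conservation_params(pseudocount = 0)
  full <- js_divergence_column(rep("W", 40), prm)
  half <- js_divergence_column(c(rep("W", 20), rep("-", 20)), prm)
  expect_equal(half, 0.5 * full, tolerance = 1e-10)
})

test_that("window smoothing with lambda 0 reproduces raw scores", {
  gen <- make_msa(msa_spec(n_rows = 40, n_cols = 30, seed = 67))
  pr0 <- conservation_profile(gen$msa, conservation_params(lambda = 0))
  expect_equal(pr0$windowed, pr0$raw_js)
  pr5 <- conservation_profile(gen$msa, conservation_params(lambda = 0.5))
  expect_false(isTRUE(all.equal(pr5$windowed, pr5$raw_js)))
})

test_that("planted conserved columns are recovered on the benchmark alignment", {
  gen <- make_msa(msa_spec(seed = 68))        # 100 rows, 110 columns
  pr <- conservation_profile(gen$msa)
  called <- pr$column[pr$conserved]
  sens <- mean(gen$conserved_cols %in% called)
  fpr <- mean(setdiff(seq_len(110), gen$conserved_cols) %in% called)
  expect_equal(sens, 1.0)
  expect_lte(fpr, 0.05)
})

test_that("the nonsynonymous fraction vetoes and admits conservation calls", {
  # 15% nonsynonymous residues: veto despite a high windowed score
  col_bad <- c(rep("A", 85), rep("W", 15))    # BLOSUM62 A/W = -3
  m_bad <- msa(apply(matrix(rep(col_bad, 21), ncol = 21), 1, paste,
                     collapse = ""), ids = paste0("s", 1:100))
  pr_bad <- conservation_profile(m_bad)
  expect_true(all(pr_bad$frac_nonsyn >= 0.10))
  expect_false(any(pr_bad$conserved))
  # 8% conservative (BLOSUM62 > 0) substitutions: conserved
  col_ok <- c(rep("I", 92), rep("V", 8))      # BLOSUM62 I/V = +3
  m_ok <- msa(apply(matrix(rep(col_ok, 21), ncol = 21), 1, paste,
                    collapse = ""), ids = paste0("s", 1:100))
  pr_ok <- conservation_profile(m_ok)
  expect_true(all(pr_ok$frac_nonsyn < 0.10))
  expect_true(all(pr_ok$conserved))
})

test_that("two frequent mutually similar residues form a pair consensus", {
  col <- c(rep("I", 55), rep("V", 45))
  m <- msa(apply(matrix(rep(col, 15), ncol = 15), 1, paste, collapse = ""),
           ids = paste0("s", 1:100))
  pr <- conservation_profile(m)
  expect_true(all(pr$consensus == "I/V"))
  expect_true(all(pr$frac_nonsyn == 0))
})

test_that("tiering assigns the highest applicable conservation level", {
  prof <- function(resnos, conserved_at) {
    data.frame(column = seq_along(resnos), ref_resnum = resnos,
               ref_aa = "A", raw_js = 0.5, windowed = 0.5,
               consensus = "A", frac_nonsyn = 0,
               conserved = resnos %in% conserved_at,
               stringsAsFactors = FALSE)
  }
  resnos <- 1:10
  tiers <- tier_columns(paralog_profile = prof(resnos, c(2, 4, 6, 8)),
                        family_profile = prof(resnos, c(4, 6)),
                        universal_profile = prof(resnos, 6))
  expect_equal(tiers$tier[tiers$ref_resnum == 6], "universal")
  expect_equal(tiers$tier[tiers$ref_resnum == 4], "family")
  expect_equal(tiers$tier[tiers$ref_resnum == 2], "paralog")
  expect_equal(tiers$tier[tiers$ref_resnum == 1], "none")
})

test_that("reference-row mapping carries author numbers through gaps", {
  m <- msa(c(ref = "AC-DE", other = "ACQDE"), ref_id = "ref",
           ref_auth_start = 1201L)
  pr <- conservation_profile(m)
  expect_equal(pr$ref_resnum, c(1201L, 1202L, NA, 1203L, 1204L))
  expect_equal(pr$ref_aa, c("A", "C", NA, "D", "E"))
})
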