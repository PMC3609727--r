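test_that("pairwise_diff applies pairwise deletion", {
  expect_equal(pairwise_diff("ACGT", "ACGA"), c(differences = 1, sites = 4))
  expect_equal(pairwise_diff("AC-T", "ACGT"), c(differences = 0, sites = 3))
  expect_equal(pairwise_diff("ANGT", "ACGT"), c(differences = 0, sites = 3))
  expect_error(pairwise_diff("ACG", "ACGT"), "length mismatch")
})

test_that("nucleotide_diversity matches hand computation and the n = 2 form", {
  id <- dna_alignment(rep(strrep("ACGT", 10), 3), paste0("s", 1:3))
  res <- nucleotide_diversity(id)
  expect_equal(res$pi, 0)
  expect_equal(res$var_pi, 0)

  # n = 2, L = 100 comparable, 2 differences: pi = 0.02,
  # Var = pi/L + pi^2 = 0.0002 + 0.0004 = 0.0006 exactly
  a <- strrep("A", 100)
  b <- paste0(strrep("A", 98), "CC")
  res <- nucleotide_diversity(dna_alignment(c(a, b), c("x", "y")))
  expect_equal(res$pi, 0.02)
  expect_equal(res$var_pi, 6e-4)
  expect_equal(res$L_mean, 100)

  expect_error(nucleotide_diversity(dna_alignment(a, "x")), ">= 2")
  expect_error(
    nucleotide_diversity(dna_alignment(c("A---", "-CGT"), c("x", "y"))),
    "no comparable sites.*x.*y")
})

test_that("pi matches the established pairwise-distance oracle", {
  for (seed in 1:5) {
    aln <- random_alignment(5, 80, seed)
    res <- nucleotide_diversity(aln)
    dna <- ape::as.DNAbin(radrate:::alignment_matrix(aln))
    d <- ape::dist.dna(dna, model = "raw", pairwise.deletion = TRUE)
    expect_equal(res$pi, mean(d))
    # and the brute-force all-pairs loop over pairwise_diff
    pairs <- utils::combn(length(aln$labels), 2)
    props <- apply(pairs, 2, function(p) {
      pd <- pairwise_diff(aln$seqs[p[1]], aln$seqs[p[2]])
      pd["differences"] / pd["sites"]
    })
    expect_equal(res$pi, mean(props))
  }
})

test_that("pi is invariant under reordering and relabeling", {
  aln <- random_alignment(6, 60, seed = 11)
  set.seed(1)
  perm <- sample(6)
  shuffled <- dna_alignment(aln$seqs[perm], paste0("z", 1:6))
  expect_equal(nucleotide_diversity(shuffled)$pi,
               nucleotide_diversity(aln)$pi)
})

test_that("variance formula behaves as documented in its limits", {
  # var_pi = 0 iff pi = 0 under the adopted total-variance formula
  aln <- random_alignment(4, 50, seed = 21)
  res <- nucleotide_diversity(aln)
  expect_gt(res$pi, 0)
  expect_gt(res$var_pi, 0)
  # as L -> infinity at fixed pi and n, the stochastic term persists:
  # Var -> 2 (n^2 + n + 3) / (9 n (n - 1)) * pi^2
  n <- res$n_seq; pi <- res$pi
  limit <- 2 * (n^2 + n + 3) / (9 * n * (n - 1)) * pi^2
  sampling <- (n + 1) / (3 * (n - 1) * res$L_mean) * pi
  expect_equal(res$var_pi, limit + sampling)
})

test_that("ms_crown_rate reproduces printed examples and its properties", {
  expect_equal(round_half_away(ms_crown_rate(10, 1.81), 2), 0.89)
  expect_equal(round_half_away(ms_crown_rate(34, 2.56), 2), 1.11)
  expect_equal(ms_crown_rate(2, 17.3), 0)
  expect_error(ms_crown_rate(1, 1), "n < 2")
  expect_error(ms_crown_rate(10, 0), "> 0")
  expect_error(ms_crown_rate(10, 1, epsilon = 0.5), "not implemented")
  # strictly decreasing in t, increasing in n
  set.seed(2)
  n <- sample(3:200, 20); t <- runif(20, 0.1, 10)
  expect_true(all(ms_crown_rate(n, t) > ms_crown_rate(n, t * 1.1)))
  expect_true(all(ms_crown_rate(n + 1, t) > ms_crown_rate(n, t)))
})

test_that("ms_stem_rate identities and stem >= crown", {
  expect_equal(ms_stem_rate(1, 5), 0)
  expect_equal(ms_stem_rate(exp(1), 1), 1)
  set.seed(3)
  n <- sample(2:500, 50); t <- runif(50, 0.05, 20)
  expect_true(all(ms_stem_rate(n, t) >= ms_crown_rate(n, t)))
})

test_that("species extrapolation reproduces the sampled-fraction ratio", {
  expect_identical(extrapolate_species(34), 101L)
  expect_identical(extrapolate_species(25), 74L)
  expect_identical(extrapolate_species(169), 500L)
  expect_error(extrapolate_species(0), ">= 1")
  expect_error(extrapolate_species(200), ">= k_clade")
})

test_that("rate-diversity correlation matches the definitional oracle", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(correlate_rate_diversity(x, 2 * x + 1)$r, 1)
  expect_equal(correlate_rate_diversity(x, -x)$r, -1)
  expect_error(correlate_rate_diversity(x, rep(1, 5)), "zero variance")
  expect_error(correlate_rate_diversity(x, 1:4), "equal length")
  set.seed(4)
  a <- rnorm(12); b <- rnorm(12)
  got <- correlate_rate_diversity(a, b)
  r_def <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(got$r, r_def)
  tstat <- r_def * sqrt((12 - 2) / (1 - r_def^2))
  expect_equal(got$p, 2 * stats::pt(-abs(tstat), 12 - 2))
})

test_that("summarize_clade assembles fields equal to stage-wise recomputation", {
  d <- sim_dataset(12, n_tips = 10, seq_length = 400)
  aln <- simulate_sequences(d$tree, d$cfg)
  calib <- calibration_spec(25, 21.1, 29.3)
  fit <- estimate_chronogram(d$tree, calib, pl_config(seq_length = 400))
  tips <- extract_clade(fit$tree, fit$tree$tip.label[1:4])$tree$tip.label
  cl <- clade_definition("demo", tips, n_min = length(tips))
  row <- summarize_clade(fit, aln, cl, calib)

  age <- crown_age(fit, tips)
  expect_equal(row$age, age)
  expect_equal(row$age_alt, age * 0.8)
  expect_equal(c(row$ci_low, row$ci_high),
               unname(propagate_calibration_ci(age, calib)))
  expect_equal(row$n_max, extrapolate_species(length(tips)))
  expect_equal(row$dr_min, ms_crown_rate(length(tips), age))
  expect_equal(row$dr_max, ms_crown_rate(row$n_max, age))
  expect_equal(row$dr_alt_min, ms_crown_rate(length(tips), age * 0.8))
  sub <- dna_alignment(aln$seqs[match(tips, aln$labels)], tips)
  div <- nucleotide_diversity(sub)
  expect_equal(row$pi, div$pi)
  expect_equal(row$var_pi, div$var_pi)
  expect_equal(row$n_seq, div$n_seq)
  expect_true(row$monophyletic)
  expect_gte(row$dr_max, row$dr_min)
  # literature count suppresses extrapolation
  cl2 <- clade_definition("demo2", tips, n_min = length(tips),
                          n_max_known = length(tips) + 5L)
  expect_equal(summarize_clade(fit, aln, cl2, calib)$n_max,
               length(tips) + 5L)

  # degenerate: clade of two identical sequences
  aln2 <- dna_alignment(c(aln$seqs[match(tips[1], aln$labels)],
                          aln$seqs[match(tips[1], aln$labels)],
                          aln$seqs[-match(tips[1:2], aln$labels)]),
                        aln$labels[c(match(tips[1:2], aln$labels),
                                     setdiff(seq_along(aln$labels),
                                             match(tips[1:2], aln$labels)))])
  row2 <- summarize_clade(fit, aln2, clade_definition("twin", tips[1:2], 2),
                          calib)
  expect_equal(row2$pi, 0)
  expect_true(is.finite(row2$dr_min) && is.finite(row2$dr_max))
  expect_gte(row2$n_max, row2$n_min)
})

test_that("published DR/CI cells are recomputable within propagated rounding", {
  # The printed table's derived columns come from unrounded ages; from the
  # PRINTED age-25 column they are recoverable exactly for the fully
  # rounding-robust rows and to within the propagated input-rounding bound
  # |dDR| <= DR * 0.005 / age + half an output ulp everywhere.
  tab <- poa_reference()
  rha <- function(x) round_half_away(x, 2)
  robust <- c("Arctagrostis", "Catabrosa/Paracolpodium", "Cinna", "Poa III")
  for (i in seq_len(nrow(tab))) {
    r <- tab[i, ]
    comp <- unname(c(rha(ms_crown_rate(r$n_min, r$age25)),
              rha(ms_crown_rate(r$n_max, r$age25)),
              rha(ms_crown_rate(r$n_min, 0.8 * r$age25)),
              rha(ms_crown_rate(r$n_max, 0.8 * r$age25)),
              rha(propagate_calibration_ci(r$age25, poa_calibration()))))
    printed <- c(r$dr25_min, r$dr25_max, r$dr20_min, r$dr20_max,
                 r$ci_low, r$ci_high)
    bound <- c(comp[1:4] * 0.005 / c(r$age25, r$age25, 0.8 * r$age25,
                                     0.8 * r$age25),
               0.005 * c(21.1, 29.3) / 25) + 0.005 + 1e-9
    expect_true(all(abs(comp - printed) <= pmax(bound, 0.01 + 1e-9)),
                label = paste("row", r$clade))
    if (r$clade %in% robust)
      expect_equal(comp, unname(printed), label = paste("robust row", r$clade))
  }
})
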