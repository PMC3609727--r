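# Per-clade statistics: Nei's nucleotide diversity with variance,
# Magallon-Sanderson crown-group diversification rates, sampled-fraction
# species extrapolation, and the rate-diversity correlation.

#' Round half away from zero
#'
#' Report-time rounding rule (0.45 -> 0.5 at one digit, symmetric for
#' negatives), as opposed to base R's round-half-even. Used for all printed
#' ages, rates and extrapolated species numbers.
#'
#' @param x Numeric vector.
#' @param digits Decimal digits (default 0).
#' @return Rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 0L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Pairwise differences between two aligned sequences
#'
#' Counts columns where both symbols are unambiguous bases (A/C/G/T) and,
#' among those, columns where the bases differ. Gaps and IUPAC ambiguity
#' codes are excluded pairwise (pairwise deletion).
#'
#' @param seq_a,seq_b Aligned sequences (character scalars of equal length).
#' @return Named integer vector `c(differences, sites)`.
#' @export
pairwise_diff <- function(seq_a, seq_b) {
  a <- strsplit(toupper(seq_a), "", fixed = TRUE)[[1]]
  b <- strsplit(toupper(seq_b), "", fixed = TRUE)[[1]]
  if (length(a) != length(b))
    stop("sequence length mismatch: ", length(a), " vs ", length(b))
  ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  c(differences = sum(a[ok] != b[ok]), sites = sum(ok))
}

#' Nei's nucleotide diversity and its variance
#'
#' Computes \eqn{\pi} as the mean over all sequence pairs of the per-pair
#' proportion of differing sites (pairwise deletion of gaps/ambiguities),
#' and the total variance
#' \deqn{Var(\pi) = \frac{n+1}{3(n-1)L}\pi + \frac{2(n^2+n+3)}{9n(n-1)}\pi^2}
#' where `n` is the number of sequences and `L` the number of sites
#' compared. With pairwise deletion no single L exists; by default L is the
#' mean number of pairwise-compared sites (the least surprising reduction).
#' `complete_deletion = TRUE` restricts both \eqn{\pi} and L to columns that
#' are unambiguous bases in every sequence.
#'
#' @param aln A [dna_alignment()] with >= 2 sequences.
#' @param complete_deletion Use only columns comparable across all sequences.
#' @return A list of class `diversity_result`: `pi`, `var_pi`, `n_seq`,
#'   `L_mean`.
#' @export
nucleotide_diversity <- function(aln, complete_deletion = FALSE) {
  stopifnot(inherits(aln, "dna_alignment"))
  n <- length(aln$labels)
  if (n < 2L) stop("nucleotide diversity requires >= 2 sequences")
  m <- alignment_matrix(aln)
  base <- m == "A" | m == "C" | m == "G" | m == "T"
  if (complete_deletion) {
    keep <- colSums(base) == n
    m <- m[, keep, drop = FALSE]
    base <- base[, keep, drop = FALSE]
  }
  dsum <- 0
  Lsum <- 0
  npair <- 0L
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ok <- base[i, ] & base[j, ]
    sites <- sum(ok)
    if (sites == 0L)
      stop("no comparable sites for pair '", aln$labels[i], "' vs '",
           aln$labels[j], "'")
    dsum <- dsum + sum(m[i, ok] != m[j, ok]) / sites
    Lsum <- Lsum + sites
    npair <- npair + 1L
  }
  pi <- dsum / npair
  L <- Lsum / npair
  var_pi <- (n + 1) / (3 * (n - 1) * L) * pi +
    2 * (n^2 + n + 3) / (9 * n * (n - 1)) * pi^2
  structure(list(pi = pi, var_pi = var_pi, n_seq = n, L_mean = L),
            class = "diversity_result")
}

#' @export
print.diversity_result <- function(x, ...) {
  cat(sprintf("pi = %.4f (var %.6f), n = %d sequences, mean L = %.1f sites\n",
              x$pi, x$var_pi, x$n_seq, x$L_mean))
  invisible(x)
}

#' Magallon-Sanderson crown-group net diversification rate
#'
#' Zero-extinction crown estimator \eqn{r = (\ln n - \ln 2)/t} for a crown
#' group of `n` extant species and crown age `t` Myr. Only the relative
#' extinction fraction `epsilon = 0` is implemented; a nonzero value raises
#' an error rather than silently approximating.
#'
#' @param n Species count (>= 2; the crown estimator is undefined below 2).
#' @param t Crown age in Myr (> 0).
#' @param epsilon Relative extinction fraction; must be 0.
#' @return Net diversification rate in species per Myr (full precision;
#'   round at report time).
#' @export
ms_crown_rate <- function(n, t, epsilon = 0) {
  if (any(epsilon != 0))
    stop("epsilon > 0 is not implemented (only the zero-extinction estimator)")
  if (any(n < 2)) stop("crown estimator undefined for n < 2")
  if (any(t <= 0)) stop("crown age must be > 0")
  (log(n) - log(2)) / t
}

#' Magallon-Sanderson stem-group net diversification rate
#'
#' Zero-extinction stem variant \eqn{r = \ln(n)/t}; provided for
#' completeness (the crown estimator is what the report table uses).
#'
#' @param n Species count (>= 1).
#' @param t Stem age in Myr (> 0).
#' @return Net diversification rate in species per Myr.
#' @export
ms_stem_rate <- function(n, t) {
  if (any(n < 1)) stop("n must be >= 1")
  if (any(t <= 0)) stop("stem age must be > 0")
  log(n) / t
}

#' Extrapolate a clade's species number from sampling fractions
#'
#' Scales the number of sampled species in a clade by the genus-wide
#' sampled fraction: `round(k_clade * n_total / k_total_sampled)`, rounding
#' half away from zero. The defaults are the study design for *Poa* (169 of
#' about 500 species sequenced); clades whose true richness is known from
#' the literature should use that number instead.
#'
#' @param k_clade Sampled species in the clade (>= 1).
#' @param k_total_sampled Total sampled species in the group (>= k_clade).
#' @param n_total Total known species in the group.
#' @return Integer species estimate.
#' @export
extrapolate_species <- function(k_clade, k_total_sampled = 169L,
                                n_total = 500L) {
  if (any(k_clade < 1)) stop("k_clade must be >= 1")
  if (any(k_total_sampled < k_clade))
    stop("k_total_sampled must be >= k_clade")
  as.integer(round_half_away(k_clade * n_total / k_total_sampled))
}

#' Correlation between diversification rate and nucleotide diversity
#'
#' Pearson product-moment correlation with the two-sided t-test p-value,
#' used to ask whether faster-diversifying clades are also more
#' molecularly diverse.
#'
#' @param rates Numeric vector of clade diversification rates.
#' @param pis Numeric vector of clade nucleotide diversities (same length,
#'   >= 3).
#' @return List with `r` (correlation), `p` (two-sided p-value), `n`.
#' @export
correlate_rate_diversity <- function(rates, pis) {
  if (length(rates) != length(pis)) stop("vectors must have equal length")
  if (length(rates) < 3L) stop("need at least 3 clades")
  if (sd(rates) == 0 || sd(pis) == 0)
    stop("zero variance in rates or diversities")
  ct <- cor.test(rates, pis, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(rates))
}

#' Assemble the full per-clade summary row
#'
#' Combines crown age under the fitted calibration, rescaling to an
#' alternative root age, calibration-CI propagation, nucleotide diversity
#' over the clade's sequences, diversification rates under minimal and
#' maximal species numbers at both calibrations, and the extrapolated
#' maximal species number (used only when `n_max_known` is absent).
#'
#' @param chrono A `chronogram` fitted at the primary calibration (e.g. a
#'   25 Myr root).
#' @param aln A [dna_alignment()] containing the clade's sequences.
#' @param clade A [clade_definition()].
#' @param calib The [calibration_spec()] used for the fit (provides the CI).
#' @param alt_root_age Alternative root age in Myr for the rescaled age
#'   columns (default 20).
#' @param k_total_sampled,n_total Extrapolation constants, see
#'   [extrapolate_species()].
#' @param complete_deletion Passed to [nucleotide_diversity()].
#' @return A one-row `data.frame` (full precision; round at report time)
#'   with columns `clade`, `n_min`, `n_max`, `n_seq`, `pi`, `var_pi`,
#'   `age_alt`, `dr_alt_min`, `dr_alt_max`, `age`, `ci_low`, `ci_high`,
#'   `dr_min`, `dr_max`, `monophyletic`.
#' @export
summarize_clade <- function(chrono, aln, clade, calib,
                            alt_root_age = 20,
                            k_total_sampled = 169L, n_total = 500L,
                            complete_deletion = FALSE) {
  stopifnot(inherits(chrono, "chronogram"),
            inherits(clade, "clade_definition"))
  ext <- extract_clade(chrono$tree, clade)
  age <- crown_age(chrono, clade)
  age_alt <- age * alt_root_age / chrono$root_age
  ci <- propagate_calibration_ci(age, calib)
  seq_idx <- match(clade$tips, aln$labels)
  if (anyNA(seq_idx))
    stop("clade '", clade$name, "': sequences missing from alignment: ",
         paste(clade$tips[is.na(seq_idx)], collapse = ", "))
  div <- nucleotide_diversity(
    dna_alignment(aln$seqs[seq_idx], aln$labels[seq_idx]),
    complete_deletion = complete_deletion)
  n_max <- if (!is.na(clade$n_max_known)) clade$n_max_known
           else extrapolate_species(clade$n_min, k_total_sampled, n_total)
  data.frame(clade = clade$name,
             n_min = clade$n_min, n_max = n_max, n_seq = div$n_seq,
             pi = div$pi, var_pi = div$var_pi,
             age_alt = age_alt,
             dr_alt_min = ms_crown_rate(clade$n_min, age_alt),
             dr_alt_max = ms_crown_rate(n_max, age_alt),
             age = age, ci_low = unname(ci["low"]),
             ci_high = unname(ci["high"]),
             dr_min = ms_crown_rate(clade$n_min, age),
             dr_max = ms_crown_rate(n_max, age),
             monophyletic = ext$monophyletic,
             stringsAsFactors = FALSE)
}
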