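# Design-evaluation metrics: sequence recovery, amino-acid distribution
# divergence (KL, per-residue log-likelihood differences), design
# confusion matrices and per-residue perplexity, optionally stratified by
# membrane region.

#' Construct a set of native/designed sequence pairs
#'
#' @param native,designed character vectors of equal-length sequences
#'   (pairwise equal lengths).
#' @param regions optional list of per-position region label vectors
#'   ("lipid", "interface", "aqueous"), same lengths as the sequences.
#' @return object of class `sequence_pair_set`.
#' @export
sequence_pair_set <- function(native, designed, regions = NULL) {
  if (length(native) != length(designed))
    stop("native and designed must have the same number of sequences")
  nat <- strsplit(native, "")
  des <- strsplit(designed, "")
  if (any(lengths(nat) != lengths(des)))
    stop("paired sequences must have equal length")
  if (!is.null(regions)) {
    if (length(regions) != length(nat) ||
        any(lengths(regions) != lengths(nat)))
      stop("region labels must cover every position of every pair")
  }
  base::structure(list(native = nat, designed = des, regions = regions),
                  class = "sequence_pair_set")
}

# flatten a pair set to per-position vectors, applying an optional subset
# filter: NULL (all), a region name, or a logical/integer selector applied
# to the flattened positions
flatten_pairs <- function(pairs, subset = NULL) {
  nat <- unlist(pairs$native, use.names = FALSE)
  des <- unlist(pairs$designed, use.names = FALSE)
  reg <- if (!is.null(pairs$regions)) unlist(pairs$regions, use.names = FALSE)
  keep <- rep(TRUE, length(nat))
  if (!is.null(subset)) {
    if (is.character(subset) && length(subset) >= 1 &&
        all(subset %in% c("lipid", "interface", "aqueous"))) {
      if (is.null(reg)) stop("pair set carries no region labels")
      keep <- reg %in% subset
    } else if (is.logical(subset)) {
      keep <- rep_len(subset, length(nat))
    } else if (is.numeric(subset)) {
      keep <- seq_along(nat) %in% subset
    } else stop("unsupported subset filter")
  }
  list(native = nat[keep], designed = des[keep],
       regions = if (!is.null(reg)) reg[keep])
}

#' Sequence recovery
#'
#' Fraction of positions at which the designed residue equals the native
#' residue, over an optional position subset (e.g. one membrane region).
#'
#' @param pairs a [sequence_pair_set()].
#' @param subset NULL, a region name ("lipid", "interface", "aqueous"), or
#'   a logical/integer position filter.
#' @return fraction in [0, 1].
#' @export
sequence_recovery <- function(pairs, subset = NULL) {
  fl <- flatten_pairs(pairs, subset)
  if (!length(fl$native)) stop("no positions pass the subset filter")
  mean(fl$native == fl$designed)
}

#' Amino-acid frequency distribution
#'
#' Per-type probabilities over the 20 canonical amino acids, pooled over
#' all positions (optionally filtered).
#'
#' @param sequences character vector of sequences, or a
#'   [sequence_pair_set()] with `which = "native"` or `"designed"`.
#' @param subset position filter as in [sequence_recovery()] (pair sets
#'   only).
#' @param which for pair sets, which side to tabulate.
#' @return named numeric vector of 20 probabilities summing to 1.
#' @export
aa_distribution <- function(sequences, subset = NULL, which = "designed") {
  if (inherits(sequences, "sequence_pair_set")) {
    fl <- flatten_pairs(sequences, subset)
    chars <- fl[[which]]
  } else {
    chars <- unlist(strsplit(sequences, ""), use.names = FALSE)
  }
  if (!length(chars)) stop("no positions to tabulate")
  tab <- table(factor(chars, levels = aa_codes()))
  as.numeric(tab) / length(chars) -> p
  stats::setNames(p, aa_codes())
}

#' Kullback-Leibler divergence between design and native distributions
#'
#' `D_KL = sum_s p_s log(p_s / q_s)` with the convention `0 log 0 = 0`,
#' plus the per-type log-likelihood differences `D_s = log(p_s / q_s)`
#' (negative = under-enriched in designs) and their sum `D`. Types with
#' zero probability on either side have undefined `D_s`; they are excluded
#' from `D` with a warning unless a pseudo-count is supplied.
#'
#' @param p_des,q_nat probability vectors over the 20 canonical amino acids
#'   (named or in [aa_codes()] order), each summing to 1 within 1e-6.
#' @param base logarithm base for D_KL and D_s (default natural log).
#' @param pseudocount optional count fraction added to both distributions
#'   before the ratio (default 0 = off).
#' @return list with `d_kl`, `d_s` (named, NA where undefined), `d`
#'   (sum of defined D_s) and `undefined` (codes excluded).
#' @export
kl_divergence <- function(p_des, q_nat, base = exp(1), pseudocount = 0) {
  fix <- function(p) {
    if (!is.null(names(p))) p <- p[aa_codes()]
    p <- as.numeric(p)
    if (length(p) != 20) stop("distributions must cover the 20 amino acids")
    if (abs(sum(p) - 1) > 1e-6) stop("distribution does not sum to 1")
    p
  }
  p <- fix(p_des); q <- fix(q_nat)
  if (pseudocount > 0) {
    p <- (p + pseudocount) / sum(p + pseudocount)
    q <- (q + pseudocount) / sum(q + pseudocount)
  }
  lg <- function(x) log(x, base = base)
  terms <- ifelse(p == 0, 0, p * lg(p / q))
  if (any(p > 0 & q == 0)) {
    warning("design distribution has support where native has none; D_KL is infinite")
    terms[p > 0 & q == 0] <- Inf
  }
  d_kl <- sum(terms)
  d_s <- stats::setNames(rep(NA_real_, 20), aa_codes())
  ok <- p > 0 & q > 0
  d_s[ok] <- lg(p[ok] / q[ok])
  undef <- aa_codes()[!ok]
  if (length(undef) && pseudocount == 0)
    warning("D_s undefined (zero probability) for: ",
            paste(undef, collapse = ", "), "; excluded from D")
  list(d_kl = d_kl, d_s = d_s, d = sum(d_s[ok]), undefined = undef)
}

#' Design confusion matrix
#'
#' 20 x 20 table `p(s | r)`: the probability that a native residue of type
#' `r` (row) is designed to type `s` (column), estimated by counting over
#' all (optionally region-filtered) positions. Rows whose native type never
#' occurs are flagged undefined (NA) rather than fatal.
#'
#' @param pairs a [sequence_pair_set()].
#' @param subset position filter as in [sequence_recovery()].
#' @return object of class `confusion_matrix`: 20 x 20 matrix with
#'   attributes `counts` (row totals) and `undefined_rows`.
#' @export
design_confusion <- function(pairs, subset = NULL) {
  fl <- flatten_pairs(pairs, subset)
  codes <- aa_codes()
  tab <- table(factor(fl$native, levels = codes),
               factor(fl$designed, levels = codes))
  counts <- rowSums(tab)
  P <- sweep(unclass(tab), 1, pmax(counts, 1), `/`)
  P[counts == 0, ] <- NA_real_
  base::structure(P, class = c("confusion_matrix", "matrix", "array"),
                  counts = counts,
                  undefined_rows = codes[counts == 0])
}

#' Per-residue design perplexity
#'
#' `pp_r = 2^(-sum_s p(s|r) log2 p(s|r))` with `0 log 0 = 0`: the
#' effective number of residue choices the design model entertains for a
#' native type. 1 for a one-hot row (fully confident), 20 for a uniform
#' row (maximally confused).
#'
#' @param row a probability row of a [design_confusion()] matrix (or any
#'   vector summing to 1), or a full `confusion_matrix` (then one value per
#'   defined row is returned).
#' @return perplexity value(s) in [1, 20].
#' @export
perplexity <- function(row) {
  if (inherits(row, "confusion_matrix")) {
    ok <- !is.na(unclass(row)[, 1])
    out <- rep(NA_real_, nrow(row))
    names(out) <- rownames(row)
    out[ok] <- apply(unclass(row)[ok, , drop = FALSE], 1, perplexity)
    return(out)
  }
  p <- as.numeric(row)
  if (any(p < 0)) stop("probabilities must be non-negative")
  if (abs(sum(p) - 1) > 1e-6) stop("row does not sum to 1")
  h <- -sum(ifelse(p == 0, 0, p * log2(p)))
  2^h
}

#' Full design-metrics report
#'
#' Sequence recovery, distribution divergence and per-residue perplexity,
#' overall and per membrane region when labels are present.
#'
#' @param pairs a [sequence_pair_set()].
#' @param base log base for the divergence (default natural).
#' @return list with `recovery`, `divergence`, `perplexity`, `confusion`,
#'   and a `regions` sublist when labels are present.
#' @export
design_metrics <- function(pairs, base = exp(1)) {
  one <- function(subset) {
    conf <- design_confusion(pairs, subset)
    div <- suppressWarnings(kl_divergence(
      aa_distribution(pairs, subset, which = "designed"),
      aa_distribution(pairs, subset, which = "native"), base = base))
    list(recovery = sequence_recovery(pairs, subset),
         divergence = div, confusion = conf,
         perplexity = perplexity(conf))
  }
  out <- one(NULL)
  if (!is.null(pairs$regions)) {
    present <- unique(unlist(pairs$regions, use.names = FALSE))
    out$regions <- lapply(stats::setNames(nm = present), one)
  }
  out
}
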