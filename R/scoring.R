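#' Adjusted Tanimoto coefficient between two microenvironment vectors
#'
#' Let `a` and `b` be the numbers of nonzero cells of the two vectors and
#' `c` the number of cells that are nonzero in both and "similar" — the two
#' values differ by less than one background standard deviation for that
#' cell (cells with zero background STD require exact equality). The score
#' is `c / (a + b - c)`, the fraction of similar cells among the cells
#' nonzero in either vector; it lies in `[0, 1]`, with `Tc(v, v) = 1`.
#'
#' @param va,vb Numeric vectors of equal length.
#' @param stats A `property_stats` (per-cell STDs), or a numeric vector of
#'   STDs of the same length.
#' @param zero_tol Magnitude below which a cell counts as zero
#'   (default 1e-12).
#' @return The adjusted Tanimoto coefficient.
#' @examples
#' stats <- structure(list(std = rep(1, 6), n_samples = 2),
#'                    class = "property_stats")
#' tanimoto(c(2, 0, 3, 1, 0, 5), c(2.5, 0, 0, 1.8, 0, 5.2), stats)  # 0.75
#' @export
tanimoto <- function(va, vb, stats, zero_tol = 1e-12) {
  std <- if (inherits(stats, "property_stats")) stats$std else as.numeric(stats)
  if (length(va) != length(vb) || length(va) != length(std)) {
    stop("vectors and property stats must share length")
  }
  nza <- abs(va) > zero_tol
  nzb <- abs(vb) > zero_tol
  a <- sum(nza)
  b <- sum(nzb)
  similar <- ifelse(std > 0, abs(va - vb) < std, va == vb)
  c_ <- sum(nza & nzb & similar)
  denom <- a + b - c_
  if (denom == 0) stop("Tanimoto undefined: both vectors are all-zero")
  c_ / denom
}

#' Background-normalized microenvironment similarity S(Tc)
#'
#' The raw Tc is mapped through the fitted background normal of its pair
#' type as the log ratio of survival functions anchored at `tc0`:
#' `S(Tc) = ln( SF(Tc) / SF(tc0) )` with `SF(x) = 1 - CDF(x)`. Since `tc0`
#' is the mode (mean) of the fitted normal, `S(tc0) = 0`, `S` is strictly
#' decreasing in Tc, negative beyond `tc0`, and changes most rapidly in the
#' upper tail; more negative values indicate similarity rarer under the
#' background. The computation is carried out on the log scale, so deep
#' tails do not underflow.
#'
#' @param tc Raw Tc value(s).
#' @param bg A `pair_background` (fields `mu`, `sigma`, `tc0`).
#' @param base Logarithm base (default `exp(1)`, the natural log).
#' @return Numeric S(Tc) value(s); 0 at `tc0`, negative above it.
#' @export
normalize_score <- function(tc, bg, base = exp(1)) {
  stopifnot(is.finite(bg$sigma), bg$sigma > 0)
  lsf <- stats::pnorm(tc, mean = bg$mu, sd = bg$sigma,
                      lower.tail = FALSE, log.p = TRUE)
  lsf0 <- stats::pnorm(bg$tc0, mean = bg$mu, sd = bg$sigma,
                       lower.tail = FALSE, log.p = TRUE)
  s <- lsf - lsf0
  s[!is.finite(s)] <- log(.Machine$double.xmin)  # survival underflow guard
  s / log(base)
}

#' Align two pockets by mutual-best microenvironment matching
#'
#' S(Tc) is computed exhaustively for every permissible cross pair (types in
#' the same physicochemical group). A pair (Ai, Bj) is matched when its
#' score is the best (most negative) of Ai's row and of Bj's column and is
#' below `cutoff`. Ties within a row or column are broken by higher raw Tc,
#' then lexicographic partner name. The binding-site similarity score is
#' the sum of matched S(Tc) values; more negative means more similar.
#'
#' @param pa,pb `microenv_set` objects featurized under the model's schema.
#' @param model A `background_model` covering every permissible pair type
#'   present (a missing fit for an encountered permissible pair type is an
#'   error naming the type).
#' @param cutoff Alignment cutoff on S(Tc) (default -0.3): only pairs with
#'   `S < cutoff` are eligible.
#' @return Object of class `pocket_alignment`: list with `matches` (data
#'   frame name_a, name_b, pair_type, raw_tc, s), `total_score`, `cutoff`,
#'   `n_a`, `n_b`.
#' @export
align_pockets <- function(pa, pb, model, cutoff = -0.3) {
  stopifnot(inherits(pa, "microenv_set"), inherits(pb, "microenv_set"),
            inherits(model, "background_model"))
  na <- nrow(pa$vectors)
  nb <- nrow(pb$vectors)
  smat <- matrix(Inf, na, nb)
  tmat <- matrix(NA_real_, na, nb)
  if (na > 0 && nb > 0) {
    for (i in seq_len(na)) {
      for (j in seq_len(nb)) {
        if (!is_comparable(pa$tags[i], pb$tags[j], model$partition)) next
        bg <- background_for_pair(model, pa$tags[i], pb$tags[j])
        tc <- tanimoto(pa$vectors[i, ], pb$vectors[j, ], model$stats)
        tmat[i, j] <- tc
        smat[i, j] <- normalize_score(tc, bg)
      }
    }
  }
  matches <- .mutual_best_matches(smat, tmat, pa$names, pb$names, cutoff)
  if (nrow(matches) > 0L) {
    matches$pair_type <- pair_key(pa$tags[matches$i], pb$tags[matches$j])
    matches <- data.frame(name_a = pa$names[matches$i],
                          name_b = pb$names[matches$j],
                          pair_type = matches$pair_type,
                          raw_tc = matches$raw_tc, s = matches$s,
                          stringsAsFactors = FALSE)
  } else {
    matches <- data.frame(name_a = character(0), name_b = character(0),
                          pair_type = character(0), raw_tc = numeric(0),
                          s = numeric(0), stringsAsFactors = FALSE)
  }
  structure(list(matches = matches,
                 total_score = if (nrow(matches)) sum(matches$s) else 0,
                 cutoff = cutoff, n_a = na, n_b = nb),
            class = "pocket_alignment")
}

# single-pass mutual-best matching with deterministic tie-breaks:
# best of a row/column is the entry with minimal s, ties resolved by
# higher raw Tc, then lexicographically smaller partner name
.mutual_best_matches <- function(smat, tmat, names_a, names_b, cutoff) {
  na <- nrow(smat)
  nb <- ncol(smat)
  empty <- data.frame(i = integer(0), j = integer(0), raw_tc = numeric(0),
                      s = numeric(0))
  if (na == 0L || nb == 0L) return(empty)
  best_in <- function(svec, tvec, partner_names) {
    ok <- is.finite(svec)
    if (!any(ok)) return(NA_integer_)
    idx <- which(ok)
    o <- order(svec[idx], -tvec[idx], partner_names[idx])
    idx[o[1]]
  }
  row_best <- vapply(seq_len(na), function(i) {
    best_in(smat[i, ], tmat[i, ], names_b)
  }, integer(1))
  col_best <- vapply(seq_len(nb), function(j) {
    best_in(smat[, j], tmat[, j], names_a)
  }, integer(1))
  rows <- empty
  for (i in seq_len(na)) {
    j <- row_best[i]
    if (is.na(j)) next
    if (!is.na(col_best[j]) && col_best[j] == i && smat[i, j] < cutoff) {
      rows <- rbind(rows, data.frame(i = i, j = j, raw_tc = tmat[i, j],
                                     s = smat[i, j]))
    }
  }
  rows
}

#' @export
print.pocket_alignment <- function(x, ...) {
  cat(sprintf("pocket_alignment: %d matches (of %d x %d), total score %.4f (cutoff %.2f)\n",
              nrow(x$matches), x$n_a, x$n_b, x$total_score, x$cutoff))
  invisible(x)
}

#' Write an alignment table (TSV)
#'
#' One row per matched microenvironment pair (names, pair type, raw Tc,
#' S(Tc)) and a footer comment line with the binding-site similarity score.
#'
#' @param alignment A `pocket_alignment`.
#' @param path File path.
#' @export
write_alignment <- function(alignment, path) {
  con <- file(path, "w")
  on.exit(close(con))
  utils::write.table(alignment$matches, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeLines(sprintf("# total_score\t%.6f", alignment$total_score), con)
  invisible(path)
}

#' Fit a normal distribution to binding-site similarity scores
#'
#' @param scores Numeric vector of binding-site similarity scores.
#' @param min_scores Minimum number of scores (default 30).
#' @return Object of class `site_score_distribution`: list with `mu`,
#'   `sigma`, `n`.
#' @export
fit_score_distribution <- function(scores, min_scores = 30) {
  scores <- as.numeric(scores)
  if (length(scores) < min_scores) {
    stop(sprintf("need at least %d scores to fit the distribution, got %d",
                 min_scores, length(scores)))
  }
  sigma <- stats::sd(scores)
  if (!is.finite(sigma) || sigma <= 0) stop("degenerate score variance")
  structure(list(mu = mean(scores), sigma = sigma, n = length(scores)),
            class = "site_score_distribution")
}

#' Lower-tail p-value of a binding-site similarity score
#'
#' More negative scores indicate stronger similarity, so significance is the
#' lower-tail normal probability of observing a score at least as negative.
#'
#' @param score Binding-site similarity score(s).
#' @param d A `site_score_distribution`.
#' @return Probability in `[0, 1]`.
#' @export
site_p_value <- function(score, d) {
  stats::pnorm((score - d$mu) / d$sigma)
}
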