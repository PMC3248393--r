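#' Enumerate positive site pairs
#'
#' All unordered pairs of a set of sites that share a binding property
#' (count `n(n-1)/2`); e.g. the 247 adenine-binding sites of the retrieval
#' benchmark give 30381 positive pairs.
#'
#' @param ids Character vector of unique site identifiers.
#' @return Data frame with columns `a`, `b`, `label` (= "positive").
#' @export
enumerate_positive_pairs <- function(ids) {
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop("site ids must be unique")
  n <- length(ids)
  if (n < 2L) {
    return(data.frame(a = character(0), b = character(0),
                      label = character(0), stringsAsFactors = FALSE))
  }
  idx <- utils::combn(n, 2)
  data.frame(a = ids[idx[1, ]], b = ids[idx[2, ]], label = "positive",
             stringsAsFactors = FALSE)
}

#' Enumerate control site pairs
#'
#' The full cross product of a positive and a negative site set (count
#' `|pos| * |neg|`); e.g. 247 adenine sites against 101 non-adenine cavities
#' give 24947 control pairs.
#'
#' @param pos_ids,neg_ids Disjoint character vectors of site identifiers.
#' @return Data frame with columns `a`, `b`, `label` (= "control").
#' @export
enumerate_control_pairs <- function(pos_ids, neg_ids) {
  pos_ids <- as.character(pos_ids)
  neg_ids <- as.character(neg_ids)
  if (length(intersect(pos_ids, neg_ids)) > 0L) {
    stop("positive and negative site sets must be disjoint")
  }
  if (length(pos_ids) == 0L || length(neg_ids) == 0L) {
    return(data.frame(a = character(0), b = character(0),
                      label = character(0), stringsAsFactors = FALSE))
  }
  grid <- expand.grid(a = pos_ids, b = neg_ids, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  data.frame(a = grid$a, b = grid$b, label = "control",
             stringsAsFactors = FALSE)
}

#' ROC analysis of scored site pairs
#'
#' Binding-site similarity scores are oriented so that more negative means
#' more similar; a pair is predicted positive when its score falls at or
#' below a threshold. The AUC is the rank (Mann-Whitney) statistic: the
#' probability that a random positive pair scores more negatively than a
#' random negative pair, ties counting one half. Sensitivity at a requested
#' specificity is the best sensitivity over thresholds achieving at least
#' that specificity.
#'
#' @param scores Numeric scores (more negative = predicted positive).
#' @param labels Logical or character labels; `TRUE`/`"positive"` marks
#'   positive pairs.
#' @param specificities Specificity levels to report sensitivity at
#'   (default `c(0.80, 0.95, 0.995)`).
#' @return Object of class `roc_result`: list with `auc`, `curve` (data
#'   frame threshold/sensitivity/specificity), `sensitivity_at` (named
#'   numeric), `n_pos`, `n_neg`.
#' @export
roc <- function(scores, labels, specificities = c(0.80, 0.95, 0.995)) {
  stopifnot(length(scores) == length(labels))
  pos <- if (is.logical(labels)) labels else labels %in% c("positive", "pos", "1", "TRUE")
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  if (n_pos == 0L || n_neg == 0L) {
    stop("ROC requires both positive and negative labels")
  }
  # rank statistic on -score (higher -score = predicted positive)
  r <- rank(-scores)
  auc <- (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  thr <- sort(unique(scores))
  curve <- data.frame(
    threshold = c(-Inf, thr),
    sensitivity = c(0, vapply(thr, function(t) mean(scores[pos] <= t),
                              numeric(1))),
    specificity = c(1, vapply(thr, function(t) mean(scores[!pos] > t),
                              numeric(1))))
  sens_at <- vapply(specificities, function(sp) {
    ok <- curve$specificity >= sp
    if (!any(ok)) 0 else max(curve$sensitivity[ok])
  }, numeric(1))
  names(sens_at) <- sprintf("spec_%g", specificities)
  structure(list(auc = auc, curve = curve, sensitivity_at = sens_at,
                 n_pos = n_pos, n_neg = n_neg), class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("roc_result: AUC %.4f (%d positives vs %d negatives)\n",
              x$auc, x$n_pos, x$n_neg))
  for (nm in names(x$sensitivity_at)) {
    cat(sprintf("  sensitivity at %s: %.3f\n",
                sub("spec_", "specificity ", nm), x$sensitivity_at[[nm]]))
  }
  invisible(x)
}

#' Upper-tail hypergeometric probability
#'
#' Probability of drawing at least `k` positives in `n` draws without
#' replacement from a population of `N` containing `K` positives; used to
#' assess whether positives concentrate at the top of a ranked pair list.
#'
#' @param N Population size.
#' @param K Positives in the population.
#' @param n Number of draws.
#' @param k Observed positives among the draws (may be a vector).
#' @return `P(X >= k)`, one probability per element of `k`.
#' @examples
#' hypergeometric_tail(10, 3, 3, 3)  # 1/120
#' @export
hypergeometric_tail <- function(N, K, n, k) {
  stopifnot(length(N) == 1, length(K) == 1, length(n) == 1, length(k) >= 1)
  if (any(c(N, K, n, k) < 0) || K > N || n > N || any(k > min(K, n))) {
    stop("infeasible hypergeometric arguments: need 0 <= k <= min(K, n) <= N")
  }
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Filter site pairs to functionally and structurally distant kinases
#'
#' Keeps pairs whose EC sub-subgroups (the first four EC fields) differ and
#' whose pairwise structural-alignment identity is at most 30 percent. An
#' incomplete EC number (a dash among the first four fields) compares
#' unequal to any complete sub-subgroup; two identical incomplete ECs are
#' treated as equal (the pair is dropped). Pairs without a PID entry are
#' skipped with a warning.
#'
#' @param sites Data frame with columns `id`, `ec`, `gene`.
#' @param pid Symmetric numeric matrix of pairwise identity percentages with
#'   site ids as dimnames, or a data frame with columns `a`, `b`, `pid`.
#' @param max_pid Identity ceiling in percent (default 30, inclusive).
#' @return Data frame of retained pairs: `a`, `b`, `gene_a`, `gene_b`,
#'   `ec_a`, `ec_b`, `pid`, `label` (= "unknown").
#' @export
filter_kinase_pairs <- function(sites, pid, max_pid = 30) {
  stopifnot(all(c("id", "ec", "gene") %in% names(sites)))
  pid_lookup <- .pid_lookup(pid)
  subsub <- vapply(sites$ec, .ec_subsubgroup, character(1))
  n <- nrow(sites)
  out <- list()
  skipped <- 0L
  for (i in seq_len(max(n - 1L, 0L))) {
    for (j in (i + 1L):n) {
      if (.same_subsubgroup(subsub[i], subsub[j])) next
      p <- pid_lookup(sites$id[i], sites$id[j])
      if (is.na(p)) { skipped <- skipped + 1L; next }
      if (p > max_pid) next
      out[[length(out) + 1L]] <- data.frame(
        a = sites$id[i], b = sites$id[j],
        gene_a = sites$gene[i], gene_b = sites$gene[j],
        ec_a = sites$ec[i], ec_b = sites$ec[j],
        pid = p, label = "unknown", stringsAsFactors = FALSE)
    }
  }
  if (skipped > 0L) {
    warning(sprintf("%d pair(s) skipped: no PID entry", skipped))
  }
  if (length(out) == 0L) {
    return(data.frame(a = character(0), b = character(0),
                      gene_a = character(0), gene_b = character(0),
                      ec_a = character(0), ec_b = character(0),
                      pid = numeric(0), label = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

.ec_subsubgroup <- function(ec) {
  fields <- strsplit(trimws(ec), ".", fixed = TRUE)[[1]]
  if (length(fields) < 4L) fields <- c(fields, rep("-", 4L - length(fields)))
  paste(fields[1:4], collapse = ".")
}

.same_subsubgroup <- function(a, b) {
  incomplete_a <- grepl("-", a, fixed = TRUE)
  incomplete_b <- grepl("-", b, fixed = TRUE)
  if (incomplete_a != incomplete_b) return(FALSE)  # incomplete != any complete
  identical(a, b)
}

.pid_lookup <- function(pid) {
  if (is.matrix(pid)) {
    function(a, b) {
      if (!(a %in% rownames(pid)) || !(b %in% colnames(pid))) return(NA_real_)
      pid[a, b]
    }
  } else {
    stopifnot(all(c("a", "b", "pid") %in% names(pid)))
    key <- c(paste(pid$a, pid$b, sep = "\r"), paste(pid$b, pid$a, sep = "\r"))
    val <- c(pid$pid, pid$pid)
    function(a, b) {
      hit <- match(paste(a, b, sep = "\r"), key)
      if (is.na(hit)) NA_real_ else val[hit]
    }
  }
}

#' Label site pairs from assay measurements
#'
#' A compound "qualifies" on a kinase when its measurement passes the
#' source-appropriate rule: for CHEMBL-style rows (after discarding rows
#' with confidence below 7, or missing), Kd < 1 uM, IC50 < 1 uM, or
#' inhibition above 90 percent at 1 uM; for Ambit-style rows, Kd < 1 uM and
#' an off-target/primary-target Kd ratio below 100, the primary target being
#' the compound's minimum-Kd target unless a `primary` column marks one. A
#' pair is `positive` when at least one shared compound qualifies on both
#' kinases, `unknown` when either kinase has no assay rows at all, and
#' `negative` otherwise. Named non-selective compounds (default
#' staurosporine) are removed first.
#'
#' @param pairs Data frame with columns `a`, `b` (kinase/site ids, matching
#'   `assays$target`).
#' @param assays Data frame of assay records with columns `compound`,
#'   `target`, `measure` (one of `"Kd"`, `"IC50"`, `"inhibition"`), `value`,
#'   `units` (`"pM"`, `"nM"`, `"uM"`, `"mM"`, `"M"`, or `"%"` for
#'   inhibition), `source` (`"chembl"` or `"ambit"`) and optionally
#'   `confidence` and `primary`.
#' @param compound_blacklist Compounds removed before labeling.
#' @return `pairs` with a `label` column (`positive`/`negative`/`unknown`).
#' @export
label_assay_pairs <- function(pairs, assays,
                              compound_blacklist = "staurosporine") {
  stopifnot(all(c("a", "b") %in% names(pairs)))
  assays <- .normalize_assays(assays, compound_blacklist)
  targets_with_data <- unique(assays$target)
  qual <- .qualifying_pairs(assays)
  qual_key <- paste(qual$compound, qual$target, sep = "\r")
  label <- character(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    a <- pairs$a[i]
    b <- pairs$b[i]
    if (!(a %in% targets_with_data) || !(b %in% targets_with_data)) {
      label[i] <- "unknown"
      next
    }
    compounds_a <- qual$compound[qual$target == a]
    shared <- compounds_a[paste(compounds_a, b, sep = "\r") %in% qual_key]
    label[i] <- if (length(shared) > 0L) "positive" else "negative"
  }
  pairs$label <- label
  pairs
}

.UNIT_TO_UM <- c(pM = 1e-6, nM = 1e-3, uM = 1, mM = 1e3, M = 1e6)

.normalize_assays <- function(assays, blacklist) {
  need <- c("compound", "target", "measure", "value", "units", "source")
  stopifnot(all(need %in% names(assays)))
  assays <- assays[!(tolower(assays$compound) %in% tolower(blacklist)), ,
                   drop = FALSE]
  if (!"confidence" %in% names(assays)) {
    assays[["confidence"]] <- rep(NA_real_, nrow(assays))
  }
  conc <- assays$measure %in% c("Kd", "IC50")
  um <- .UNIT_TO_UM[assays$units]
  bad <- conc & (is.na(um) | is.na(assays$value) | assays$value <= 0)
  bad <- bad | (!conc & (assays$units != "%" | is.na(assays$value) |
                           assays$value < 0 | assays$value > 100))
  if (any(bad)) {
    warning(sprintf("%d assay row(s) rejected: unparseable units or values",
                    sum(bad)))
    assays <- assays[!bad, , drop = FALSE]
    um <- um[!bad]
    conc <- conc[!bad]
  }
  assays$value_um <- ifelse(conc, assays$value * um, NA_real_)
  assays
}

# (compound, target) pairs passing the source-appropriate inhibition rule
.qualifying_pairs <- function(assays) {
  ch <- assays[assays$source == "chembl", , drop = FALSE]
  ch <- ch[!is.na(ch$confidence) & ch$confidence >= 7, , drop = FALSE]
  ch_ok <- (ch$measure %in% c("Kd", "IC50") & ch$value_um < 1) |
    (ch$measure == "inhibition" & ch$value > 90)
  ch <- ch[ch_ok, c("compound", "target"), drop = FALSE]

  am <- assays[assays$source == "ambit" & assays$measure == "Kd", ,
               drop = FALSE]
  am_rows <- list()
  if (nrow(am) > 0L) {
    for (cmp in unique(am$compound)) {
      sub <- am[am$compound == cmp, , drop = FALSE]
      if ("primary" %in% names(sub) && any(sub$primary %in% TRUE)) {
        kd_primary <- min(sub$value_um[sub$primary %in% TRUE])
      } else {
        kd_primary <- min(sub$value_um)
      }
      ok <- sub$value_um < 1 & (sub$value_um / kd_primary) < 100
      am_rows[[length(am_rows) + 1L]] <-
        sub[ok, c("compound", "target"), drop = FALSE]
    }
  }
  out <- rbind(ch, do.call(rbind, am_rows))
  if (is.null(out) || nrow(out) == 0L) {
    return(data.frame(compound = character(0), target = character(0),
                      stringsAsFactors = FALSE))
  }
  unique(out)
}

#' Ranked significance report for scored site pairs
#'
#' Sorts pairs by ascending binding-site similarity score (most similar
#' first), attaches lower-tail p-values from a fitted score distribution,
#' flags pairs below the p-value cutoff, and cross-tabulates the flagged
#' pairs against their labels: `true_positive` (flagged, labeled positive),
#' `false_positive` (flagged, labeled negative) and `novel` (flagged, no
#' experimental data). When both positive and negative labels are present,
#' the hypergeometric upper-tail probability of the positives' concentration
#' among the flagged labeled pairs is reported.
#'
#' @param scored_pairs Data frame with columns `a`, `b`, `score` and
#'   optionally `label` (`positive`/`negative`/`unknown`; missing column
#'   means all unknown).
#' @param dist A `site_score_distribution` from [fit_score_distribution()].
#' @param p_cutoff Significance cutoff (default 0.01).
#' @return Object of class `rank_report`: list with `table` (ranked data
#'   frame with `p_value`, `significant`, `category`), `counts` (named
#'   category counts), `separation_p` (hypergeometric p or `NA`).
#' @export
rank_report <- function(scored_pairs, dist, p_cutoff = 0.01) {
  stopifnot(all(c("a", "b", "score") %in% names(scored_pairs)))
  tab <- scored_pairs
  if (!"label" %in% names(tab)) tab$label <- "unknown"
  tab <- tab[order(tab$score), , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  tab$p_value <- site_p_value(tab$score, dist)
  tab$significant <- tab$p_value < p_cutoff
  tab$category <- ifelse(!tab$significant, "not_significant",
                  ifelse(tab$label == "positive", "true_positive",
                  ifelse(tab$label == "negative", "false_positive", "novel")))
  labeled <- tab$label %in% c("positive", "negative")
  sep_p <- NA_real_
  if (any(tab$label == "positive") && any(tab$label == "negative")) {
    N <- sum(labeled)
    K <- sum(tab$label == "positive")
    n_drawn <- sum(labeled & tab$significant)
    k_obs <- sum(tab$label == "positive" & tab$significant)
    if (n_drawn > 0L) sep_p <- hypergeometric_tail(N, K, n_drawn, k_obs)
  }
  counts <- table(factor(tab$category,
                         levels = c("true_positive", "false_positive",
                                    "novel", "not_significant")))
  structure(list(table = tab, counts = c(counts), separation_p = sep_p),
            class = "rank_report")
}

#' @export
print.rank_report <- function(x, ...) {
  cat(sprintf("rank_report: %d pairs; %d significant (%d true positive, %d false positive, %d novel)\n",
              nrow(x$table), sum(x$table$significant),
              x$counts[["true_positive"]], x$counts[["false_positive"]],
              x$counts[["novel"]]))
  if (!is.na(x$separation_p)) {
    cat(sprintf("  ranking separation (hypergeometric upper tail): p = %.3g\n",
                x$separation_p))
  }
  invisible(x)
}
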