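#' Default residue-group partition of the 22 microenvironment types
#'
#' Microenvironment comparison is restricted to types in the same
#' physicochemical group: positively charged (R, H, K), negatively charged
#' (D, E), polar (S, T, Q, N, W1, Y1), nonpolar (A, C, G, I, L, M, P, V) and
#' aromatic (W2, Y2, F). Unordered within-group pairs, self-pairs included,
#' give the 72 permissible pair types.
#'
#' @return Named character vector mapping each of the 22 type tags to its
#'   group label.
#' @export
default_partition <- function() {
  c(R = "positive", H = "positive", K = "positive",
    D = "negative", E = "negative",
    S = "polar", T = "polar", Q = "polar", N = "polar",
    W1 = "polar", Y1 = "polar",
    A = "nonpolar", C = "nonpolar", G = "nonpolar", I = "nonpolar",
    L = "nonpolar", M = "nonpolar", P = "nonpolar", V = "nonpolar",
    W2 = "aromatic", Y2 = "aromatic", F = "aromatic")
}

#' Canonical key for an unordered pair of microenvironment types
#'
#' @param tag_a,tag_b Type tags.
#' @return Character key, order-independent (`pair_key("T","S")` equals
#'   `pair_key("S","T")`).
#' @export
pair_key <- function(tag_a, tag_b) {
  lo <- pmin(tag_a, tag_b)
  hi <- pmax(tag_a, tag_b)
  paste(lo, hi, sep = "|")
}

#' Are two microenvironment types comparable?
#'
#' True exactly when both tags belong to the same physicochemical group of
#' the partition; only such pairs are ever scored or aligned.
#'
#' @param tag_a,tag_b Type tags.
#' @param partition Named group vector as from [default_partition()].
#' @return Logical.
#' @examples
#' is_comparable("R", "K")   # TRUE  (both positively charged)
#' is_comparable("D", "K")   # FALSE (negative vs positive)
#' @export
is_comparable <- function(tag_a, tag_b, partition = default_partition()) {
  ga <- partition[tag_a]
  gb <- partition[tag_b]
  if (any(is.na(ga)) || any(is.na(gb))) {
    bad <- unique(c(tag_a[is.na(ga)], tag_b[is.na(gb)]))
    stop(sprintf("unknown microenvironment type tag(s): %s",
                 paste(bad, collapse = ", ")))
  }
  unname(ga == gb)
}

#' Enumerate the permissible pair types of a partition
#'
#' All unordered within-group pairs including self-pairs; the default
#' partition (group sizes 3, 2, 6, 8, 3) yields
#' 6 + 3 + 21 + 36 + 6 = 72 pair types.
#'
#' @param partition Named group vector as from [default_partition()].
#' @return Character vector of pair keys (see [pair_key()]).
#' @export
enumerate_pair_types <- function(partition = default_partition()) {
  keys <- character(0)
  for (g in unique(partition)) {
    tags <- sort(names(partition)[partition == g])
    for (i in seq_along(tags)) {
      for (j in i:length(tags)) {
        keys <- c(keys, pair_key(tags[i], tags[j]))
      }
    }
  }
  sort(keys)
}

#' Per-cell standard deviations of a microenvironment population
#'
#' One population standard deviation per vector cell across a reference set
#' of microenvironments; these widths define the one-STD "similar property"
#' rule of the adjusted Tanimoto score.
#'
#' @param vectors Numeric matrix (one microenvironment per row) or a
#'   `microenv_set`.
#' @return Object of class `property_stats`: list with `std` (numeric,
#'   per-cell) and `n_samples`.
#' @export
compute_property_stats <- function(vectors) {
  if (inherits(vectors, "microenv_set")) vectors <- vectors$vectors
  vectors <- as.matrix(vectors)
  n <- nrow(vectors)
  if (n < 2L) stop("need at least 2 vectors to compute property stats")
  mu <- colMeans(vectors)
  std <- sqrt(colMeans(vectors^2) - mu^2)
  std[std < 0] <- 0  # numerical guard
  structure(list(std = unname(std), n_samples = n), class = "property_stats")
}

#' Fit the background normal of one pair type
#'
#' Raw Tc scores of cross-site pairs of one pair type are summarized by a
#' normal distribution: `mu` and `sigma` are the sample mean and standard
#' deviation, and `tc0` (the Tc at which the normalized score is zero) is
#' the mode of the fitted density, i.e. its mean.
#'
#' @param tc_samples Numeric vector of raw Tc scores.
#' @param min_samples Minimum sample count (default 30).
#' @param pair_type Optional pair-type key, used in error messages.
#' @return Object of class `pair_background`: list with `mu`, `sigma`,
#'   `tc0`, `n_samples`.
#' @export
fit_pair_background <- function(tc_samples, min_samples = 30,
                                pair_type = NULL) {
  lab <- if (is.null(pair_type)) "" else sprintf(" for pair type %s", pair_type)
  tc_samples <- as.numeric(tc_samples)
  if (length(tc_samples) < min_samples) {
    stop(sprintf("too few Tc samples%s: %d < %d", lab, length(tc_samples),
                 min_samples))
  }
  mu <- mean(tc_samples)
  sigma <- stats::sd(tc_samples)
  if (!is.finite(sigma) || sigma <= 0) {
    stop(sprintf("zero-variance Tc samples%s", lab))
  }
  structure(list(mu = mu, sigma = sigma, tc0 = mu,
                 n_samples = length(tc_samples)),
            class = "pair_background")
}

#' Build a background model from featurized pockets
#'
#' Computes per-cell property standard deviations over all microenvironments,
#' then, for every permissible pair type, collects raw Tc scores of
#' cross-site microenvironment pairs (subsampled to `max_pairs_per_type`
#' with the run seed) and fits each pair type's normal background. Pair
#' types with fewer than `min_samples` cross-site pairs are reported in a
#' warning and flagged as missing in the model. Structure-level filters
#' (resolution, sequence redundancy) are the responsibility of the input
#' manifest: pockets passed here are taken as the reference set.
#'
#' @param pockets List of `microenv_set` objects, one per site, all built
#'   with the same schema.
#' @param partition Named group vector (default [default_partition()]).
#' @param schema The `property_schema` the pockets were featurized with.
#' @param seed Integer seed controlling pair subsampling.
#' @param min_samples Minimum Tc samples per pair type (default 30).
#' @param max_pairs_per_type Subsampling cap per pair type (default 50000).
#' @return Object of class `background_model`: list with `stats`
#'   (`property_stats`), `partition`, `pairs` (named list of
#'   `pair_background`), `missing_pair_types`, `provenance`.
#' @export
build_background <- function(pockets, partition = default_partition(),
                             schema = default_schema(), seed = 1L,
                             min_samples = 30, max_pairs_per_type = 50000) {
  stopifnot(length(pockets) >= 1L,
            all(vapply(pockets, inherits, logical(1), "microenv_set")))
  ncell <- schema_length(schema)
  all_vec <- do.call(rbind, lapply(pockets, `[[`, "vectors"))
  if (ncol(all_vec) != ncell) {
    stop("pocket vectors do not match the schema length")
  }
  stats <- compute_property_stats(all_vec)
  tags <- unlist(lapply(pockets, `[[`, "tags"), use.names = FALSE)
  site <- rep(seq_along(pockets),
              vapply(pockets, function(p) nrow(p$vectors), integer(1)))
  keys <- enumerate_pair_types(partition)
  fits <- stats::setNames(vector("list", length(keys)), keys)
  missing <- character(0)
  set.seed(.derive_seed(seed, "background_pairs"))
  for (key in keys) {
    tg <- strsplit(key, "|", fixed = TRUE)[[1]]
    ia <- which(tags == tg[1])
    ib <- which(tags == tg[2])
    if (length(ia) == 0L || length(ib) == 0L) {
      missing <- c(missing, key); next
    }
    cand <- expand.grid(a = ia, b = ib)
    cand <- cand[site[cand$a] != site[cand$b], , drop = FALSE]
    if (tg[1] == tg[2]) {
      cand <- cand[cand$a < cand$b, , drop = FALSE]  # unordered self-type pairs
    }
    if (nrow(cand) < min_samples) {
      missing <- c(missing, key); next
    }
    if (nrow(cand) > max_pairs_per_type) {
      cand <- cand[sample.int(nrow(cand), max_pairs_per_type), , drop = FALSE]
    }
    tc <- vapply(seq_len(nrow(cand)), function(i) {
      tanimoto(all_vec[cand$a[i], ], all_vec[cand$b[i], ], stats)
    }, numeric(1))
    fit <- tryCatch(fit_pair_background(tc, min_samples, key),
                    error = function(e) NULL)
    if (is.null(fit)) missing <- c(missing, key) else fits[[key]] <- fit
  }
  if (length(missing) > 0L) {
    warning(sprintf("background missing %d of %d pair types: %s",
                    length(missing), length(keys),
                    paste(missing, collapse = ", ")))
  }
  structure(list(
    stats = stats, partition = partition,
    pairs = fits[!vapply(fits, is.null, logical(1))],
    missing_pair_types = missing,
    provenance = list(seed = as.integer(seed), n_sites = length(pockets),
                      n_microenvironments = nrow(all_vec),
                      min_samples = min_samples,
                      max_pairs_per_type = max_pairs_per_type,
                      schema_cells = ncell)),
    class = "background_model")
}

#' @export
print.background_model <- function(x, ...) {
  cat(sprintf(
    "background_model: %d cells, %d/%d pair types fitted (%d sites, %d microenvironments)\n",
    length(x$stats$std), length(x$pairs),
    length(enumerate_pair_types(x$partition)),
    x$provenance$n_sites, x$provenance$n_microenvironments))
  invisible(x)
}

#' Look up the fitted background of a pair type
#'
#' Fails loudly for impermissible (cross-group) pairs and for permissible
#' pairs absent from the model.
#'
#' @param model A `background_model`.
#' @param tag_a,tag_b Type tags.
#' @return A `pair_background`.
#' @export
background_for_pair <- function(model, tag_a, tag_b) {
  if (!is_comparable(tag_a, tag_b, model$partition)) {
    stop(sprintf("pair (%s, %s) is not permissible: types are in different groups",
                 tag_a, tag_b))
  }
  key <- pair_key(tag_a, tag_b)
  fit <- model$pairs[[key]]
  if (is.null(fit)) {
    stop(sprintf("background model has no fit for permissible pair type %s", key))
  }
  fit
}

#' Write / read a background model
#'
#' The model is serialized as a JSON file (pair fits, partition, provenance,
#' format version) plus a TSV of per-cell standard deviations.
#'
#' @param model A `background_model`.
#' @param json_path Path of the JSON file.
#' @param std_path Path of the standard-deviation TSV; defaults to
#'   `json_path` with extension `.std.tsv`.
#' @export
write_background <- function(model, json_path,
                             std_path = sub("\\.json$", ".std.tsv", json_path)) {
  if (identical(std_path, json_path)) std_path <- paste0(json_path, ".std.tsv")
  pairs <- lapply(model$pairs, function(p) {
    list(mu = p$mu, sigma = p$sigma, tc0 = p$tc0, n_samples = p$n_samples)
  })
  obj <- list(format = "pocketalign-background-1",
              partition = as.list(model$partition),
              pairs = pairs,
              missing_pair_types = model$missing_pair_types,
              n_samples_stats = model$stats$n_samples,
              provenance = model$provenance,
              std_file = basename(std_path))
  jsonlite::write_json(obj, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  utils::write.table(
    data.frame(cell = seq_along(model$stats$std) - 1L, std = model$stats$std),
    std_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(json_path)
}

#' @rdname write_background
#' @export
read_background <- function(json_path,
                            std_path = sub("\\.json$", ".std.tsv", json_path)) {
  obj <- jsonlite::read_json(json_path, simplifyVector = FALSE)
  if (!identical(obj$format, "pocketalign-background-1")) {
    stop("unrecognized background file format")
  }
  stdtab <- utils::read.delim(std_path)
  stats <- structure(list(std = as.numeric(stdtab$std),
                          n_samples = as.integer(obj$n_samples_stats)),
                     class = "property_stats")
  pairs <- lapply(obj$pairs, function(p) {
    structure(list(mu = p$mu, sigma = p$sigma, tc0 = p$tc0,
                   n_samples = p$n_samples), class = "pair_background")
  })
  structure(list(stats = stats,
                 partition = unlist(obj$partition),
                 pairs = pairs,
                 missing_pair_types = unlist(obj$missing_pair_types) %||% character(0),
                 provenance = obj$provenance),
            class = "background_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# deterministic sub-seed derived from a run seed and a component name,
# kept below 2^31 - 1
.derive_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(seed) * 48271 + h * 1009) %% 2147483629)
}
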