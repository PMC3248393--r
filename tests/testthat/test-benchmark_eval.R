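test_that("positive-pair enumeration is n(n-1)/2", {
  ids247 <- sprintf("site%03d", 1:247)
  expect_equal(nrow(enumerate_positive_pairs(ids247)), 30381L)
  expect_equal(nrow(enumerate_positive_pairs(letters[1:4])), 6L)
  expect_equal(nrow(enumerate_positive_pairs("a")), 0L)
  expect_error(enumerate_positive_pairs(c("a", "a")), "unique")
  for (n in c(2, 17, 101, 500)) {
    expect_equal(nrow(enumerate_positive_pairs(sprintf("s%d", 1:n))),
                 n * (n - 1) / 2)
  }
})

test_that("control-pair enumeration is the full cross product", {
  pos <- sprintf("p%03d", 1:247)
  neg <- sprintf("n%03d", 1:101)
  expect_equal(nrow(enumerate_control_pairs(pos, neg)), 24947L)
  expect_equal(nrow(enumerate_control_pairs(letters[1:3], LETTERS[1:2])), 6L)
  expect_equal(nrow(enumerate_control_pairs(character(0), letters[1:5])), 0L)
  expect_error(enumerate_control_pairs(c("a", "b"), c("b", "c")), "disjoint")
})

test_that("roc reproduces hand-computable AUCs and rejects one-class input", {
  r1 <- roc(c(-5, -4, -2, -1), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(r1$auc, 1.0)
  r2 <- roc(c(-3, -1, -4, -2), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(r2$auc, 0.25)  # 1 of 4 pos-neg comparisons won
  expect_error(roc(c(-1, -2), c(TRUE, TRUE)), "both positive and negative")
})

test_that("roc equals the O(n^2) rank oracle, with ties at one half", {
  set.seed(6)
  for (rep in 1:10) {
    n <- 60
    scores <- round(rnorm(n), 1)  # rounding forces ties
    pos <- runif(n) < 0.4
    if (!any(pos) || all(pos)) next
    expect_equal(roc(scores, pos)$auc, auc_oracle(scores, pos),
                 tolerance = 1e-12)
  }
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(9)
  scores <- rnorm(200)
  pos <- runif(200) < 0.5
  a0 <- roc(scores, pos)$auc
  expect_equal(roc(3 * scores - 7, pos)$auc, a0)
  expect_equal(roc(-exp(-scores), pos)$auc, a0)
})

test_that("roc agrees with pROC on random data", {
  skip_if_not_installed("pROC")
  set.seed(14)
  scores <- rnorm(300)
  pos <- runif(300) < 0.5
  ours <- roc(scores, pos)$auc
  theirs <- as.numeric(pROC::auc(pROC::roc(
    response = pos, predictor = -scores, quiet = TRUE,
    direction = "<", levels = c(FALSE, TRUE))))
  expect_equal(ours, theirs, tolerance = 1e-10)
})

test_that("shuffled labels give chance-level AUC", {
  set.seed(25)
  scores <- rnorm(4000)
  pos <- sample(rep(c(TRUE, FALSE), 2000))
  expect_equal(roc(scores, pos)$auc, 0.5, tolerance = 0.03)
})

test_that("sensitivity at specificity follows the threshold sweep", {
  # pos scores -5..-1, neg scores -2..2 (ties broken by construction)
  scores <- c(seq(-5, -1, by = 1), seq(-2.5, 1.5, by = 1))
  pos <- rep(c(TRUE, FALSE), each = 5)
  r <- roc(scores, pos, specificities = c(0.8, 1.0))
  # at spec 1.0 the threshold must sit below every negative: 3 of 5 positives
  expect_equal(unname(r$sensitivity_at["spec_1"]), 0.6)
  expect_gte(unname(r$sensitivity_at["spec_0.8"]), 0.6)
})

test_that("hypergeometric tail matches direct combinatorics", {
  expect_equal(hypergeometric_tail(10, 3, 3, 3), 1 / 120)
  expect_equal(hypergeometric_tail(10, 3, 3, 0), 1.0)
  expect_equal(hypergeometric_tail(40, 11, 10, 9),
               hyper_tail_oracle(40, 11, 10, 9), tolerance = 1e-12)
  expect_error(hypergeometric_tail(10, 11, 3, 1), "infeasible")
  expect_error(hypergeometric_tail(10, 3, 3, 4), "infeasible")
})

test_that("kinase pair filtering applies EC and PID rules", {
  sites <- data.frame(
    id = c("2src", "3blq", "x1", "x2", "y1"),
    ec = c("2.7.10.2", "2.7.11.22", "2.7.10.1", "2.7.10.1", "2.7.11.1"),
    gene = c("SRC", "CCNT1", "G1", "G2", "G3"),
    stringsAsFactors = FALSE)
  pid <- expand.grid(a = sites$id, b = sites$id, KEEP.OUT.ATTRS = FALSE,
                     stringsAsFactors = FALSE)
  pid$pid <- 50
  pid$pid[pid$a == "2src" & pid$b == "3blq"] <- 10.24
  pid$pid[pid$a == "x1" & pid$b == "x2"] <- 12
  pid$pid[pid$a == "x1" & pid$b == "y1"] <- 31
  pid$pid[pid$a == "x2" & pid$b == "y1"] <- 30
  got <- filter_kinase_pairs(sites, pid)
  keep <- paste(got$a, got$b)
  expect_true("2src 3blq" %in% keep)   # different sub-subgroup, PID 10.24
  expect_false("x1 x2" %in% keep)      # same sub-subgroup 2.7.10.1
  expect_false("x1 y1" %in% keep)      # PID 31 > 30
  expect_true("x2 y1" %in% keep)       # PID 30 boundary kept (not higher than)
})

test_that("incomplete EC sub-subgroups compare unequal to complete ones", {
  sites <- data.frame(id = c("a", "b", "c"),
                      ec = c("2.7.1.-", "2.7.1.2", "2.7.1.-"),
                      gene = c("ga", "gb", "gc"), stringsAsFactors = FALSE)
  pid <- expand.grid(a = sites$id, b = sites$id, KEEP.OUT.ATTRS = FALSE,
                     stringsAsFactors = FALSE)
  pid$pid <- 10
  got <- filter_kinase_pairs(sites, pid)
  keep <- paste(got$a, got$b)
  expect_true("a b" %in% keep)    # incomplete vs complete: different
  expect_false("a c" %in% keep)   # identical incomplete: treated equal
})

test_that("missing PID entries are skipped with a warning", {
  sites <- data.frame(id = c("a", "b"), ec = c("2.7.10.1", "2.7.11.1"),
                      gene = c("x", "y"), stringsAsFactors = FALSE)
  pid <- data.frame(a = "a", b = "zzz", pid = 5, stringsAsFactors = FALSE)
  expect_warning(got <- filter_kinase_pairs(sites, pid), "no PID")
  expect_equal(nrow(got), 0L)
})

test_that("assay labeling implements the Ambit and CHEMBL rules", {
  pairs <- data.frame(a = c("KA", "KA", "KC"), b = c("KB", "KC", "KD"),
                      stringsAsFactors = FALSE)
  assays <- data.frame(
    compound = c("X", "X", "Y", "Y"),
    target = c("KA", "KB", "KA", "KB"),
    measure = c("Kd", "Kd", "IC50", "IC50"),
    value = c(0.5, 0.8, 2, 2),
    units = c("uM", "uM", "uM", "uM"),
    source = c("ambit", "ambit", "chembl", "chembl"),
    confidence = c(NA, NA, 8, 8),
    stringsAsFactors = FALSE)
  got <- label_assay_pairs(pairs, assays)
  expect_equal(got$label, c("positive", "unknown", "unknown"))

  # compound Y alone (IC50 2 uM > 1 uM) does not qualify -> negative
  got2 <- label_assay_pairs(data.frame(a = "KA", b = "KB"),
                            assays[assays$compound == "Y", ])
  expect_equal(got2$label, "negative")
})

test_that("CHEMBL confidence, units and inhibition thresholds are enforced", {
  pairs <- data.frame(a = "KA", b = "KB", stringsAsFactors = FALSE)
  base <- data.frame(
    compound = "Z", target = c("KA", "KB"), measure = "Kd",
    value = c(500, 700), units = "nM", source = "chembl",
    confidence = c(9, 9), stringsAsFactors = FALSE)
  expect_equal(label_assay_pairs(pairs, base)$label, "positive")  # 0.5/0.7 uM

  low_conf <- base
  low_conf$confidence <- c(9, 6)
  expect_equal(label_assay_pairs(pairs, low_conf)$label, "negative")

  inhib <- data.frame(
    compound = "W", target = c("KA", "KB"), measure = "inhibition",
    value = c(95, 91), units = "%", source = "chembl", confidence = 8,
    stringsAsFactors = FALSE)
  expect_equal(label_assay_pairs(pairs, inhib)$label, "positive")
  inhib$value <- c(95, 90)  # boundary: must exceed 90
  expect_equal(label_assay_pairs(pairs, inhib)$label, "negative")
})

test_that("Ambit off/primary ratio and staurosporine blacklist apply", {
  pairs <- data.frame(a = "KA", b = "KB", stringsAsFactors = FALSE)
  wide <- data.frame(
    compound = "V", target = c("KA", "KB"), measure = "Kd",
    value = c(0.005, 0.9), units = "uM", source = "ambit",
    stringsAsFactors = FALSE)
  # ratio 0.9/0.005 = 180 >= 100: KB does not qualify
  expect_equal(label_assay_pairs(pairs, wide)$label, "negative")

  stau <- data.frame(
    compound = "staurosporine", target = c("KA", "KB"), measure = "Kd",
    value = c(0.01, 0.01), units = "uM", source = "ambit",
    stringsAsFactors = FALSE)
  expect_equal(label_assay_pairs(pairs, stau)$label, "unknown")
})

test_that("assay labeling is order-independent and rejects bad units", {
  pairs <- data.frame(a = "KA", b = "KB", stringsAsFactors = FALSE)
  assays <- data.frame(
    compound = c("X", "X", "B"), target = c("KA", "KB", "KA"),
    measure = "Kd", value = c(0.2, 0.3, 1), units = c("uM", "uM", "furlong"),
    source = "ambit", stringsAsFactors = FALSE)
  expect_warning(l1 <- label_assay_pairs(pairs, assays), "rejected")
  expect_warning(l2 <- label_assay_pairs(pairs, assays[c(3, 1, 2), ]),
                 "rejected")
  expect_equal(l1$label, l2$label)
  expect_equal(l1$label, "positive")
})

test_that("rank_report flags by p-value and cross-tabulates labels", {
  d <- structure(list(mu = -2, sigma = 0.5, n = 100L),
                 class = "site_score_distribution")
  scores <- data.frame(
    a = sprintf("s%d", 1:5), b = sprintf("t%d", 1:5),
    score = c(-3.5, -3.4, -2.1, -2.0, -1.5),
    label = c("positive", "negative", "positive", "unknown", "negative"),
    stringsAsFactors = FALSE)
  rep1 <- rank_report(scores, d, p_cutoff = 0.01)
  expected_sig <- site_p_value(scores$score, d) < 0.01
  expect_equal(sum(rep1$table$significant), sum(expected_sig))
  expect_equal(rep1$table$score, sort(scores$score))
  expect_equal(unname(rep1$counts["true_positive"]), 1L)
  expect_equal(unname(rep1$counts["false_positive"]), 1L)
  # hypergeometric separation over labeled pairs: N=4, K=2, n=2, k=1
  expect_equal(rep1$separation_p, hyper_tail_oracle(4, 2, 2, 1),
               tolerance = 1e-12)

  # all labels unknown: only novel/not_significant categories appear
  scores$label <- "unknown"
  rep2 <- rank_report(scores, d, p_cutoff = 0.01)
  expect_true(all(rep2$table$category %in% c("novel", "not_significant")))
  expect_true(is.na(rep2$separation_p))
})

test_that("constructed rankings yield the expected separation p-value", {
  # 40 labeled pairs, 11 positives; positives at ranks 1-8 and 10 among the
  # significant set of size 10 -> k = 9
  d <- structure(list(mu = 0, sigma = 1, n = 100L),
                 class = "site_score_distribution")
  score <- seq(-6, -6 + 39 * 0.05, by = 0.05)  # all well below mu
  label <- rep("negative", 40)
  label[c(1:8, 10)] <- "positive"
  label[c(15, 20)] <- "positive"  # the other 2 of 11 positives
  tab <- data.frame(a = sprintf("a%d", 1:40), b = sprintf("b%d", 1:40),
                    score = score, label = label, stringsAsFactors = FALSE)
  # cutoff chosen so exactly the first 10 ranked pairs are significant
  pcut <- site_p_value(score[10], d) + 1e-12
  rep3 <- rank_report(tab, d, p_cutoff = pcut)
  expect_equal(sum(rep3$table$significant), 10L)
  expect_equal(rep3$separation_p, hyper_tail_oracle(40, 11, 10, 9),
               tolerance = 1e-12)
})
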