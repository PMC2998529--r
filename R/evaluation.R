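# Benchmark harness: negative-pair sampling, ROC/AUC by the trapezoidal
# rule, F1 by score cutoff, F1-improvement ratios, topology-cutoff grid
# search, and Fisher-z-averaged expression correlation.

pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

#' Sample a negative (non-interacting) pair set
#'
#' Draws `n` distinct unordered gene pairs uniformly from
#' `universe x universe`, excluding self-pairs and every pair present in
#' `known_positives`. The seed makes the draw reproducible; it is
#' recorded in the result's attributes.
#'
#' @param universe Character vector of gene ids.
#' @param known_positives Data frame (two columns of gene ids) or list of
#'   pairs that must not be sampled.
#' @param n Number of negative pairs.
#' @param seed Integer seed for the draw.
#' @return Data frame with columns `gene_a`, `gene_b`.
#' @export
build_negative_set <- function(universe, known_positives, n, seed) {
  universe <- sort(unique(as.character(universe)))
  if (n == 0L) {
    out <- data.frame(gene_a = character(0), gene_b = character(0))
    attr(out, "seed") <- seed
    return(out)
  }
  known <- if (is.data.frame(known_positives) && nrow(known_positives)) {
    pair_key(as.character(known_positives[[1L]]),
             as.character(known_positives[[2L]]))
  } else character(0)
  m <- length(universe)
  n_candidates <- m * (m - 1) / 2 - length(unique(known))
  if (n > n_candidates) {
    stop("cannot sample ", n, " negative pairs: only ", n_candidates,
         " candidate pairs exist for ", m, " genes and ",
         length(unique(known)), " known positives")
  }
  out_a <- character(0); out_b <- character(0)
  seen <- character(0)
  withr_seed(seed, {
    # rejection sampling; falls back to full enumeration for small universes
    tries <- 0L
    while (length(out_a) < n && tries < 50L) {
      k <- (n - length(out_a)) * 3L + 10L
      i <- sample.int(m, k, replace = TRUE)
      j <- sample.int(m, k, replace = TRUE)
      ok <- i != j
      a <- pmin(universe[i[ok]], universe[j[ok]])
      b <- pmax(universe[i[ok]], universe[j[ok]])
      keys <- pair_key(a, b)
      keep <- !(keys %in% known) & !(keys %in% seen) & !duplicated(keys)
      a <- a[keep]; b <- b[keep]; keys <- keys[keep]
      take <- seq_len(min(length(a), n - length(out_a)))
      out_a <- c(out_a, a[take]); out_b <- c(out_b, b[take])
      seen <- c(seen, keys[take])
      tries <- tries + 1L
    }
    if (length(out_a) < n) {
      all_pairs <- utils::combn(universe, 2L)
      keys <- pair_key(all_pairs[1L, ], all_pairs[2L, ])
      avail <- which(!(keys %in% known) & !(keys %in% seen))
      extra <- sample(avail, n - length(out_a))
      out_a <- c(out_a, all_pairs[1L, extra])
      out_b <- c(out_b, all_pairs[2L, extra])
    }
  })
  out <- data.frame(gene_a = out_a, gene_b = out_b,
                    stringsAsFactors = FALSE)
  attr(out, "seed") <- seed
  out
}

# run code under a local RNG seed without disturbing the global stream
withr_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  eval.parent(substitute(code))
}

#' ROC curve and area under it
#'
#' Sweeps a threshold over all distinct scores (classification rule:
#' `score >= threshold` predicts positive; tied scores are grouped at one
#' threshold), computes the confusion matrix, TPR, FPR, precision and F1
#' at each threshold, and the AUC by the trapezoidal rule over the
#' (FPR, TPR) points including (0,0) and (1,1). Pairs with `NA` scores
#' (unscorable) are excluded and counted in `n_unscored`.
#'
#' @param scores Numeric vector.
#' @param labels Logical or 0/1 vector, `TRUE`/1 = positive.
#' @return An `eval_curve`: list with `points` (data frame threshold,
#'   TP, FP, TN, FN, tpr, fpr, precision, f1), `auc`, `n_pos`, `n_neg`,
#'   `n_unscored`.
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.logical(labels)
  ok <- !is.na(scores)
  n_unscored <- sum(!ok)
  scores <- scores[ok]; labels <- labels[ok]
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L) {
    stop("ROC undefined: need at least one positive and one negative ",
         "with scores (got ", n_pos, " / ", n_neg, ")")
  }
  thr <- sort(unique(scores), decreasing = TRUE)
  tp <- vapply(thr, function(x) sum(labels & scores >= x), 1)
  fp <- vapply(thr, function(x) sum(!labels & scores >= x), 1)
  fn <- n_pos - tp
  tn <- n_neg - fp
  tpr <- tp / (tp + fn)
  fpr <- fp / (fp + tn)
  precision <- ifelse(tp + fp > 0, tp / (tp + fp), NA_real_)
  f1 <- ifelse(!is.na(precision) & precision + tpr > 0,
               2 * precision * tpr / (precision + tpr), 0)
  xs <- c(0, fpr, 1); ys <- c(0, tpr, 1)
  auc <- sum(diff(xs) * (utils::head(ys, -1) + utils::tail(ys, -1)) / 2)
  structure(list(
    points = data.frame(threshold = thr, tp = tp, fp = fp, tn = tn,
                        fn = fn, tpr = tpr, fpr = fpr,
                        precision = precision, f1 = f1),
    auc = auc, n_pos = n_pos, n_neg = n_neg, n_unscored = n_unscored
  ), class = "eval_curve")
}

#' @export
print.eval_curve <- function(x, ...) {
  cat("eval_curve:", x$n_pos, "positives,", x$n_neg, "negatives",
      if (x$n_unscored) paste0(" (", x$n_unscored, " unscored)"),
      "\n  AUC =", round(x$auc, 4), "\n")
  invisible(x)
}

#' F1 score over a fixed cutoff grid
#'
#' At each cutoff, pairs with `score >= cutoff` are predicted positive;
#' precision, recall (TPR) and `F1 = 2 P R / (P + R)` are reported. F1 is
#' 0 where precision and recall are both 0, and `NA` where nothing is
#' predicted positive.
#'
#' @param scores,labels As in [roc_curve()].
#' @param cutoffs Numeric grid; the default 0.05..0.95 by 0.05 matches
#'   the granularity used for the similarity-score comparisons.
#' @return Data frame with columns `cutoff`, `precision`, `recall`, `f1`.
#' @export
f1_by_cutoff <- function(scores, labels, cutoffs = seq(0.05, 0.95, 0.05)) {
  labels <- as.logical(labels)
  ok <- !is.na(scores)
  scores <- scores[ok]; labels <- labels[ok]
  n_pos <- sum(labels)
  rows <- lapply(cutoffs, function(x) {
    tp <- sum(labels & scores >= x)
    fp <- sum(!labels & scores >= x)
    r <- tp / n_pos
    if (tp + fp == 0) {
      p <- NA_real_; f1 <- NA_real_
    } else {
      p <- tp / (tp + fp)
      f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
    }
    data.frame(cutoff = x, precision = p, recall = r, f1 = f1)
  })
  do.call(rbind, rows)
}

#' Average F1 improvement of one method over another
#'
#' Mean over the common cutoff grid of `F1_a / F1_b`, restricted to
#' cutoffs where `F1_b > 0`; the number of excluded cutoffs is reported
#' as an attribute.
#'
#' @param table_a,table_b Data frames from [f1_by_cutoff()] on the same
#'   grid.
#' @return The improvement ratio, with attribute `n_excluded`.
#' @export
f1_improvement <- function(table_a, table_b) {
  stopifnot(all.equal(table_a$cutoff, table_b$cutoff))
  fa <- table_a$f1; fb <- table_b$f1
  usable <- !is.na(fa) & !is.na(fb) & fb > 0
  if (!any(usable)) {
    stop("F1 improvement undefined: baseline F1 is 0 at every cutoff")
  }
  out <- mean(fa[usable] / fb[usable])
  attr(out, "n_excluded") <- sum(!usable)
  out
}

#' Grid search for the topology cutoff
#'
#' Scores a labeled benchmark with TCSS at every cutoff in the grid and
#' returns the cutoff maximizing AUC (mean F1 over the score-cutoff grid
#' is reported alongside). Ties break toward the smaller cutoff.
#'
#' @param dag,ann Ontology and annotation corpus.
#' @param benchmark Data frame `gene_a`, `gene_b`, `label` (logical or
#'   0/1).
#' @param cutoffs Numeric vector of topology cutoffs to evaluate.
#' @param combine `"max"` (default) or `"bma"`.
#' @return List with `best_cutoff`, `table` (cutoff, auc, mean_f1) and
#'   `curves` (the `eval_curve` per cutoff).
#' @export
grid_search_cutoff <- function(dag, ann, benchmark, cutoffs,
                               combine = "max") {
  if (!nrow(benchmark)) stop("empty benchmark")
  rows <- list(); curves <- list()
  dag <- transitive_reduction(dag)
  ann <- reduce_to_most_specific(ann, dag)
  for (ct in cutoffs) {
    scored <- score_gene_pairs(dag, ann, benchmark, method = "tcss",
                               combine = combine, cutoff = ct,
                               warn = FALSE)
    curve <- roc_curve(scored$score, benchmark$label)
    f1tab <- f1_by_cutoff(scored$score, benchmark$label)
    rows[[length(rows) + 1L]] <-
      data.frame(cutoff = ct, auc = curve$auc,
                 mean_f1 = mean(f1tab$f1, na.rm = TRUE))
    curves[[as.character(ct)]] <- curve
  }
  tab <- do.call(rbind, rows)
  best <- tab$cutoff[[which.max(tab$auc)]]  # which.max takes first = smallest
  list(best_cutoff = best, table = tab, curves = curves)
}

#' Fisher z transform and its inverse
#'
#' `fisher_z(r) = atanh(r) = 0.5 ln((1+r)/(1-r))`; correlations with
#' `|r| >= 1` are clamped to `1 - 1e-9` in magnitude before the
#' transform.
#'
#' @param r Correlations in \[-1, 1\].
#' @param z Transformed values.
#' @return Numeric vector.
#' @export
fisher_z <- function(r) {
  r <- pmin(pmax(r, -(1 - 1e-9)), 1 - 1e-9)
  0.5 * log((1 + r) / (1 - r))
}

#' @rdname fisher_z
#' @export
fisher_z_inverse <- function(z) {
  (exp(2 * z) - 1) / (exp(2 * z) + 1)
}

#' Averaged expression correlation per gene pair
#'
#' For each gene pair and each experiment, the Pearson correlation of the
#' two genes' expression profiles is computed, z-transformed, the
#' transforms averaged, and the average back-transformed to the r scale.
#' Following the published estimator, the default average divides the sum
#' of the `N` per-experiment transforms by `N - 1`; `denominator = "N"`
#' gives the ordinary mean.
#'
#' @param pairs Data frame of gene pairs (first two columns).
#' @param expression Named list of numeric matrices (genes x conditions),
#'   one per experiment, rownames = gene ids; or a single matrix for one
#'   experiment.
#' @param denominator `"N-1"` (as printed) or `"N"`.
#' @return `pairs` with columns `r_bar` (back-transformed average
#'   correlation, `NA` when no experiment was usable) and
#'   `n_experiments`.
#' @export
expression_correlation <- function(pairs, expression,
                                   denominator = c("N-1", "N")) {
  denominator <- match.arg(denominator)
  if (is.matrix(expression)) expression <- list(expression)
  out <- as.data.frame(pairs)
  ga <- as.character(out[[1L]]); gb <- as.character(out[[2L]])
  res <- mapply(function(a, b) {
    zs <- numeric(0)
    for (mat in expression) {
      if (!(a %in% rownames(mat)) || !(b %in% rownames(mat))) next
      xa <- mat[a, ]; xb <- mat[b, ]
      if (length(xa) < 3L || stats::sd(xa) == 0 || stats::sd(xb) == 0) next
      zs <- c(zs, fisher_z(stats::cor(xa, xb)))
    }
    if (!length(zs)) return(c(NA_real_, 0))
    n <- length(zs)
    zbar <- if (denominator == "N-1" && n > 1L) sum(zs) / (n - 1)
            else mean(zs)
    c(fisher_z_inverse(zbar), n)
  }, ga, gb)
  out$r_bar <- res[1L, ]
  out$n_experiments <- as.integer(res[2L, ])
  out
}
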