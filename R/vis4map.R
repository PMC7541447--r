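# VIS4Map: gradient saliency over complementarity-map models.
#
# For a model trained on the L x L x 7 complementarity map, the saliency of
# cell (i, j) is the L2 norm across the 7 channels of the gradient of the
# selected output head with respect to that cell, min-max normalized to
# [0, 1] (the channel reduction and the normalization are package choices;
# alternatives `max` and `abs_sum` are provided). Learned secondary
# structures appear as diagonal features. Overlap with a reference structure
# is quantified by binarizing the saliency at its top-k cells (k = number of
# reference cells by default) and intersecting with the reference pair mask;
# a shuffled-assignment null calibrates the statistic.

#' Gradient saliency map for a complementarity-map model
#'
#' @param model A trained `nn_net` consuming `L x L x 7` inputs.
#' @param input A [complementarity_map()] (or plain `L x L x 7` array).
#' @param head Output head to differentiate (default 1).
#' @param reduce Channel reduction: `"l2"` (default), `"max"`, or
#'   `"abs_sum"`.
#' @return An object of class `saliency_map`: `L x L` matrix in `[0, 1]`
#'   with attributes `head` and `reduce`. A constant model yields an all-zero
#'   map (not NaN).
#' @export
saliency <- function(model, input, head = 1L, reduce = c("l2", "max", "abs_sum")) {
  reduce <- match.arg(reduce)
  stopifnot(inherits(model, "nn_net"))
  d <- dim(input)
  if (length(d) != 3 || d[3] != 7) {
    stop("input must be an L x L x 7 complementarity map", call. = FALSE)
  }
  if (!isTRUE(all.equal(unname(model$input_shape), unname(d)))) {
    stop("model input shape (", paste(model$input_shape, collapse = "x"),
         ") does not match map (", paste(d, collapse = "x"), ")",
         call. = FALSE)
  }
  x <- array(input, dim = c(1, d))
  g <- nn_input_gradient(model, x, head = head)
  g <- array(g, dim = d)
  m <- switch(reduce,
    l2 = sqrt(apply(g^2, c(1, 2), sum)),
    max = apply(abs(g), c(1, 2), max),
    abs_sum = apply(abs(g), c(1, 2), sum)
  )
  hi <- max(m)
  if (hi > 0) m <- m / hi   # constant model -> all zeros, guarded
  structure(m, class = c("saliency_map", "matrix"),
            head = head, reduce = reduce)
}

#' Base-pair mask of a reference structure
#'
#' @param structure Dot-bracket string.
#' @return A symmetric binary `L x L` matrix with 1 at both `(i, j)` and
#'   `(j, i)` of every pair.
#' @export
structure_mask <- function(structure) {
  s <- gsub("+", "", structure, fixed = TRUE)
  L <- nchar(s)
  m <- matrix(0L, L, L)
  pr <- db_pairs(s)
  if (nrow(pr)) {
    m[pr] <- 1L
    m[pr[, c("j", "i"), drop = FALSE]] <- 1L
  }
  m
}

#' Percentage overlap between a saliency map and a reference mask
#'
#' Binarizes the saliency at its `k` highest cells (ties broken by position
#' order, deterministically) and reports `100 * |topk intersect ref| / |ref|`.
#'
#' @param sal A [saliency()] matrix.
#' @param ref A [structure_mask()] of the same dimensions.
#' @param k Top-cell budget; defaults to the number of set reference cells.
#' @return Percent overlap in `[0, 100]`.
#' @export
overlap_percent <- function(sal, ref, k = NULL) {
  stopifnot(all(dim(sal) == dim(ref)))
  nref <- sum(ref > 0)
  if (nref == 0) stop("reference mask has no pairs", call. = FALSE)
  k <- k %||% nref
  ord <- order(as.numeric(sal), decreasing = TRUE)
  top <- ord[seq_len(min(k, length(ord)))]
  100 * sum(ref[top] > 0) / nref
}

#' Matched vs shuffled saliency/structure overlap
#'
#' For each sequence, computes the overlap between its saliency map and its
#' own reference structure (matched) and between the saliency map and a
#' randomly reassigned reference from the same set (shuffled), then tests
#' separation with a one-sided Wilcoxon rank-sum test.
#'
#' @param model A trained complementarity-map `nn_net` (e.g. an MFE
#'   predictor).
#' @param seqs Character vector of sequences (padded into the model's frame).
#' @param structures Optional reference dot-bracket strings; defaults to the
#'   fold engine's MFE structures.
#' @param head Output head for the saliency gradient.
#' @param seed Seed for the shuffled assignment.
#' @return An object of class `overlap_result`: tibble `overlaps`
#'   (`seq_id`, `matched`, `shuffled`), `p_value`, `statistic`.
#' @export
matched_vs_shuffled <- function(model, seqs, structures = NULL, head = 1L,
                                seed = 1L) {
  n <- length(seqs)
  if (n < 20) warning("fewer than 20 sequences: low power", call. = FALSE)
  structures <- structures %||%
    vapply(seqs, function(s) fold_mfe(s)$structure, character(1),
           USE.NAMES = FALSE)
  L <- model$input_shape[1]
  masks <- lapply(structures, function(st) {
    m <- matrix(0L, L, L)
    sm <- structure_mask(st)
    m[seq_len(nrow(sm)), seq_len(ncol(sm))] <- sm
    m
  })
  sals <- lapply(seqs, function(s) {
    mp <- array(0, c(L, L, 7))
    cm <- complementarity_map(s)
    l <- dim(cm)[1]
    mp[seq_len(l), seq_len(l), ] <- cm
    saliency(model, mp, head = head)
  })
  set.seed(seed)
  perm <- sample.int(n)
  matched <- vapply(seq_len(n), function(i) {
    overlap_percent(sals[[i]], masks[[i]])
  }, numeric(1))
  shuffled <- vapply(seq_len(n), function(i) {
    overlap_percent(sals[[i]], masks[[perm[i]]])
  }, numeric(1))
  wt <- wilcox.test(matched, shuffled, alternative = "greater", exact = FALSE)
  structure(list(overlaps = tibble::tibble(seq_id = seq_len(n),
                                           matched = matched,
                                           shuffled = shuffled),
                 p_value = wt$p.value, statistic = unname(wt$statistic)),
            class = "overlap_result")
}

#' @export
tidy.overlap_result <- function(x, ...) {
  tidyr::pivot_longer(x$overlaps, c("matched", "shuffled"),
                      names_to = "assignment", values_to = "percent_overlap")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat("saliency/structure overlap: matched mean ",
      signif(mean(x$overlaps$matched), 4), "%, shuffled mean ",
      signif(mean(x$overlaps$shuffled), 4), "%, rank-sum p = ",
      format.pval(x$p_value), "\n", sep = "")
  invisible(x)
}

#' Average a set of saliency maps
#'
#' @param maps A list of equal-dimension matrices.
#' @return Their element-wise mean matrix.
#' @export
average_maps <- function(maps) {
  stopifnot(length(maps) >= 1)
  d <- dim(maps[[1]])
  ok <- vapply(maps, function(m) all(dim(m) == d), logical(1))
  if (!all(ok)) stop("maps must share dimensions", call. = FALSE)
  Reduce(`+`, maps) / length(maps)
}

#' Quartile-sorted averaged saliency maps
#'
#' Groups maps by quartile of an external signal (e.g. the OFF value, from
#' tight to leaky), averages within each quartile and applies a percentile
#' contrast stretch (1st-99th linear stretch by default) to visualize
#' sparsely distributed structures.
#'
#' @param maps List of saliency matrices.
#' @param values Numeric signal, one per map.
#' @param n_groups Number of quantile groups (default 4).
#' @param stretch Lower/upper percentile for contrast enhancement.
#' @return A list of averaged, contrast-stretched matrices, one per
#'   quartile (named q1 = lowest signal .. q4 = highest); empty groups are
#'   skipped with a warning.
#' @export
sort_by_signal <- function(maps, values, n_groups = 4L,
                           stretch = c(0.01, 0.99)) {
  stopifnot(length(maps) == length(values))
  brks <- quantile(values, probs = seq(0, 1, length.out = n_groups + 1))
  grp <- cut(values, breaks = unique(brks), include.lowest = TRUE,
             labels = FALSE)
  out <- list()
  for (g in seq_len(max(grp, na.rm = TRUE))) {
    ii <- which(grp == g)
    if (!length(ii)) {
      warning("empty quartile group ", g, " skipped", call. = FALSE)
      next
    }
    avg <- average_maps(maps[ii])
    lo <- quantile(avg, stretch[1]); hi <- quantile(avg, stretch[2])
    if (hi > lo) avg <- pmin(pmax((avg - lo) / (hi - lo), 0), 1)
    out[[paste0("q", g)]] <- avg
  }
  out
}
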