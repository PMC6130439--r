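#' Enumerate candidate default-to-task-positive edges
#'
#' Lists every unordered ROI pair with one endpoint in the
#' default-mode network and the other in the task-positive union
#' (scope `"dmn_to_taskpos"`) or in any non-default network (scope
#' `"dmn_to_all"`). With the packaged 333-region assignments the
#' task-positive scope yields 41 x 123 = 5,043 pairs.
#'
#' @param parcellation A [parcellation()].
#' @param scope `"dmn_to_taskpos"` or `"dmn_to_all"`.
#' @return Data frame with columns `roi_i`, `roi_j` (`roi_i < roi_j`),
#'   `net_i`, `net_j`.
#' @export
candidate_edges <- function(parcellation,
                            scope = c("dmn_to_taskpos", "dmn_to_all")) {
  scope <- match.arg(scope)
  stopifnot(inherits(parcellation, "parcellation"))
  dmn <- default_rois(parcellation)
  other <- if (scope == "dmn_to_taskpos") {
    taskpos_rois(parcellation)
  } else {
    setdiff(parcellation$roi_id, dmn)
  }
  if (length(dmn) == 0L) stop("parcellation has no Default regions")
  if (length(other) == 0L) {
    stop("parcellation has no ", if (scope == "dmn_to_taskpos")
      "task-positive" else "non-default", " regions")
  }
  grid <- expand.grid(a = dmn, b = other, KEEP.OUT.ATTRS = FALSE)
  edges <- data.frame(
    roi_i = pmin(grid$a, grid$b),
    roi_j = pmax(grid$a, grid$b)
  )
  edges <- edges[order(edges$roi_i, edges$roi_j), , drop = FALSE]
  rownames(edges) <- NULL
  edges$net_i <- parcellation$network[edges$roi_i]
  edges$net_j <- parcellation$network[edges$roi_j]
  attr(edges, "scope") <- scope
  edges
}

#' Build the anticorrelated network mask from reference scans
#'
#' Averages each candidate edge across an independent set of
#' reference connectivity matrices and retains the most anticorrelated
#' edges. Averaging is on the Fisher-z scale by default (the
#' variance-stabilized convention), converted back to r with `tanh`
#' before applying the cut so that thresholds are stated in r units;
#' `average = "r"` averages tanh-transformed values directly.
#'
#' Two selection rules are first-class: `"threshold"` keeps edges with
#' reference mean `r < r_cut`; `"density"` keeps the
#' `ceiling(fraction * n_candidates)` most negative edges, breaking
#' boundary ties deterministically by (roi_i, roi_j) lexicographic
#' order.
#'
#' @param reference_mats List of >= 2 Fisher-z connectivity matrices
#'   from the reference sample, all on the same parcellation.
#' @param parcellation A [parcellation()].
#' @param scope Edge scope, see [candidate_edges()].
#' @param rule `"threshold"` or `"density"`.
#' @param r_cut Threshold on the reference mean correlation
#'   (default -0.35).
#' @param fraction Density fraction of candidates to keep
#'   (default 0.05).
#' @param average `"z"` (default) or `"r"`: scale on which reference
#'   scans are averaged.
#' @return An `edge_mask`: data frame with columns `roi_i`, `roi_j`,
#'   `net_i`, `net_j`, `ref_mean_r`, with attributes `scope` and
#'   `rule`.
#' @export
build_mask <- function(reference_mats, parcellation,
                       scope = c("dmn_to_taskpos", "dmn_to_all"),
                       rule = c("threshold", "density"),
                       r_cut = -0.35, fraction = 0.05,
                       average = c("z", "r")) {
  scope <- match.arg(scope)
  rule <- match.arg(rule)
  average <- match.arg(average)
  if (!is.list(reference_mats) || length(reference_mats) < 2L) {
    stop("need at least 2 reference connectivity matrices")
  }
  n <- n_rois(parcellation)
  ok <- vapply(reference_mats, function(m) {
    is.matrix(m) && all(dim(m) == n)
  }, logical(1))
  if (!all(ok)) stop("reference matrices do not all match the parcellation")

  edges <- candidate_edges(parcellation, scope)
  idx <- cbind(edges$roi_i, edges$roi_j)
  vals <- vapply(reference_mats, function(m) m[idx],
                 numeric(nrow(edges)))
  vals <- matrix(vals, nrow = nrow(edges))
  edges$ref_mean_r <- if (average == "z") {
    tanh(rowMeans(vals))
  } else {
    rowMeans(tanh(vals))
  }

  keep <- if (rule == "threshold") {
    which(edges$ref_mean_r < r_cut)
  } else {
    n_keep <- as.integer(ceiling(fraction * nrow(edges)))
    # stable ordering: most negative first, lexicographic tie-break
    ord <- order(edges$ref_mean_r, edges$roi_i, edges$roi_j)
    sort(ord[seq_len(n_keep)])
  }
  if (length(keep) == 0L || any(edges$ref_mean_r[keep] >= 0)) {
    if (length(keep) == 0L) {
      stop(sprintf(
        "no edge survives the mask rule (minimum reference mean r = %.4f)",
        min(edges$ref_mean_r)))
    }
    stop("mask would retain non-negative reference edges; ",
         "loosen the rule or check the reference sample")
  }
  mask <- edges[keep, , drop = FALSE]
  rownames(mask) <- NULL
  attr(mask, "scope") <- scope
  attr(mask, "rule") <- if (rule == "threshold") {
    list(type = "threshold", r_cut = r_cut)
  } else {
    list(type = "density", fraction = fraction)
  }
  attr(mask, "average") <- average
  class(mask) <- c("edge_mask", "data.frame")
  mask
}

#' Mask density
#'
#' Retained edges as a percentage of candidate edges, rounded to the
#' nearest integer (so 250 of 5,043 reports 5).
#'
#' @param n_retained Number of edges in the mask.
#' @param n_candidates Number of candidate edges.
#' @return Integer percent density.
#' @export
mask_density_pct <- function(n_retained, n_candidates) {
  as.integer(round(100 * n_retained / n_candidates))
}

#' Region importance within a mask
#'
#' Counts, for every ROI, the mask edges incident to it (the tabular
#' analogue of colouring regions by their number of retained negative
#' connections). Counts sum to twice the number of edges.
#'
#' @param mask An `edge_mask` (any data frame with `roi_i`, `roi_j`).
#' @param n_rois Total number of ROIs; ROIs with no incident edge get
#'   a zero count. Defaults to the largest ROI id present.
#' @return Data frame with `roi_id` and `n_edges`.
#' @export
region_importance <- function(mask, n_rois = max(mask$roi_i, mask$roi_j)) {
  if (nrow(mask) == 0L) stop("mask is empty")
  counts <- tabulate(c(mask$roi_i, mask$roi_j), nbins = n_rois)
  data.frame(roi_id = seq_len(n_rois), n_edges = counts)
}

#' Averaged negative-connectivity metric for one scan
#'
#' The scan-level summary the group analyses model: the arithmetic
#' mean of the Fisher-z connectivity values over the mask edges.
#'
#' @param mat Fisher-z connectivity matrix for one scan.
#' @param mask An `edge_mask`.
#' @return Scalar mean Fisher-z value.
#' @export
average_negative_connectivity <- function(mat, mask) {
  stopifnot(is.matrix(mat), nrow(mat) == ncol(mat))
  if (max(mask$roi_j) > nrow(mat)) {
    stop("mask references ROIs beyond the matrix size")
  }
  vals <- mat[cbind(mask$roi_i, mask$roi_j)]
  if (anyNA(vals)) {
    bad <- which(is.na(vals))
    stop("undefined connectivity at mask edge(s): ",
         paste(sprintf("(%d,%d)", mask$roi_i[bad], mask$roi_j[bad]),
               collapse = ", "))
  }
  mean(vals)
}

#' Per-scan values for every mask edge
#'
#' @param mats Named list of Fisher-z connectivity matrices.
#' @param mask An `edge_mask`.
#' @return Scans x edges numeric matrix; column names `"i-j"`.
#' @export
edge_values <- function(mats, mask) {
  idx <- cbind(mask$roi_i, mask$roi_j)
  out <- t(vapply(mats, function(m) m[idx], numeric(nrow(mask))))
  colnames(out) <- paste(mask$roi_i, mask$roi_j, sep = "-")
  rownames(out) <- names(mats)
  out
}

#' Write / read an edge mask as TSV
#'
#' Columns: `roi_i`, `roi_j`, `ref_mean_r`, `net_i`, `net_j`.
#'
#' @param mask An `edge_mask`.
#' @param path File path.
#' @export
write_mask <- function(mask, path) {
  utils::write.table(
    mask[, c("roi_i", "roi_j", "ref_mean_r", "net_i", "net_j")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  mask <- utils::read.delim(path, stringsAsFactors = FALSE)
  class(mask) <- c("edge_mask", "data.frame")
  mask
}
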