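#' Network labels counted as task-positive
#'
#' The task-positive system is the union of the cingulo-opercular,
#' salience, dorsal-attention, ventral-attention and fronto-parietal
#' networks. It is disjoint from `"Default"` by construction; every
#' other label (somatomotor, visual, auditory, "None", ...) belongs to
#' neither side and never enters a default-to-task-positive edge set.
#'
#' @return Character vector of network labels.
#' @export
task_positive_networks <- function() {
  c("CinguloOperc", "Salience", "DorsalAttn", "VentralAttn", "FrontoParietal")
}

#' Construct a parcellation
#'
#' A parcellation assigns each region of interest (ROI) to exactly one
#' functional network. ROI ids must be the contiguous integers
#' `1..n_rois`, in order; columns of every time-series matrix are
#' assumed to follow this order.
#'
#' @param network Character vector of network labels, one per ROI;
#'   position `i` is the label of ROI `i`.
#' @return A `parcellation` object: a data frame with columns `roi_id`
#'   and `network`.
#' @examples
#' p <- parcellation(c("Default", "Default", "DorsalAttn", "Visual"))
#' n_rois(p)
#' @export
parcellation <- function(network) {
  network <- as.character(network)
  if (length(network) < 2L || anyNA(network) || any(!nzchar(network))) {
    stop("'network' must be a non-missing label per ROI (>= 2 ROIs)")
  }
  out <- data.frame(
    roi_id = seq_along(network),
    network = network,
    stringsAsFactors = FALSE
  )
  class(out) <- c("parcellation", "data.frame")
  out
}

#' @rdname parcellation
#' @param x A `parcellation`.
#' @export
n_rois <- function(x) {
  stopifnot(inherits(x, "parcellation"))
  nrow(x)
}

#' Read a parcellation assignment table
#'
#' Expects a TSV with columns `roi_id` and `network`. Ids must be
#' unique and exactly cover `1..n`.
#'
#' @param path Path to the TSV file.
#' @return A [parcellation()].
#' @export
read_parcellation <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("roi_id", "network")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols)) {
    stop("parcellation table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  ids <- as.integer(tab$roi_id)
  if (anyNA(ids) || anyDuplicated(ids) ||
      !identical(sort(ids), seq_len(nrow(tab)))) {
    stop("roi_id must be unique and exactly cover 1..n")
  }
  parcellation(tab$network[order(ids)])
}

#' Packaged 333-region network assignments (synthetic stand-in)
#'
#' A 333-region table whose per-network region counts follow the
#' published Gordon et al. (2016) cortical parcellation: 41 default-mode
#' regions and 123 task-positive regions (40 cingulo-opercular, 32
#' dorsal-attention, 24 fronto-parietal, 23 ventral-attention, 4
#' salience), the remaining 169 in sensory/motor/unassigned networks.
#' The table is a synthetic stand-in: network sizes match the published
#' scheme, but ROI ids are block-ordered rather than anatomically
#' ordered, so it supports every network-level computation in this
#' package (candidate-edge enumeration, masks, averaged metrics) while
#' carrying no spatial information.
#'
#' @return A [parcellation()] with 333 ROIs.
#' @examples
#' p <- gordon333_parcellation()
#' table(p$network)
#' @export
gordon333_parcellation <- function() {
  path <- system.file("extdata", "parcellation_gordon333_synthetic.tsv",
                      package = "negconn", mustWork = TRUE)
  read_parcellation(path)
}

#' ROI subsets by network side
#'
#' @param parc A [parcellation()].
#' @return Integer ROI ids in the default-mode network
#'   (`default_rois`) or in the task-positive union (`taskpos_rois`).
#' @export
default_rois <- function(parc) {
  stopifnot(inherits(parc, "parcellation"))
  parc$roi_id[parc$network == "Default"]
}

#' @rdname default_rois
#' @export
taskpos_rois <- function(parc) {
  stopifnot(inherits(parc, "parcellation"))
  parc$roi_id[parc$network %in% task_positive_networks()]
}

#' A small toy parcellation for examples and simulations
#'
#' Builds a parcellation with the given number of regions per network,
#' in block order. Defaults give 24 ROIs: 8 default-mode, 14
#' task-positive across five networks, 2 unassigned.
#'
#' @param counts Named integer vector, network label -> number of ROIs.
#' @return A [parcellation()].
#' @export
toy_parcellation <- function(counts = c(
                               Default = 8L, CinguloOperc = 4L,
                               DorsalAttn = 3L, FrontoParietal = 3L,
                               VentralAttn = 2L, Salience = 2L,
                               Other = 2L
                             )) {
  stopifnot(!is.null(names(counts)), all(counts >= 0))
  parcellation(rep(names(counts), times = counts))
}
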