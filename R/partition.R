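#' Partition nodes around the resection area
#'
#' Splits the nodes of one (band-specific) backbone into three disjoint
#' sets: `RA`, the resected nodes; `N`, the non-resected nodes adjacent to
#' at least one RA node; and `O`, all remaining nodes. The union of `N` and
#' `O` is the non-resected set (RAbar). Because adjacency changes with the
#' band, the partition is recomputed per band. Empty `N` or `O` is allowed
#' here; downstream comparisons involving an empty set are marked missing.
#'
#' @param a Binary adjacency matrix.
#' @param ra_rois Non-empty character vector of resected ROI names (all
#'   present among the matrix labels).
#' @return A tibble with `roi` and `set` (`"RA"`, `"N"` or `"O"`).
#' @export
#' @examples
#' path5 <- matrix(0, 5, 5)
#' path5[cbind(1:4, 2:5)] <- path5[cbind(2:5, 1:4)] <- 1
#' rownames(path5) <- colnames(path5) <- paste0("R", 1:5)
#' partition_nodes(path5, "R1") # N = R2, O = R3..R5
partition_nodes <- function(a, ra_rois) {
  a <- check_binary_matrix(a)
  if (length(ra_rois) == 0) stop("`ra_rois` must be non-empty", call. = FALSE)
  rois <- rownames(a)
  unknown <- setdiff(ra_rois, rois)
  if (length(unknown)) {
    stop("unknown RA ROI(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  in_ra <- rois %in% ra_rois
  touches_ra <- rowSums(a[, in_ra, drop = FALSE]) > 0
  set <- ifelse(in_ra, "RA", ifelse(touches_ra, "N", "O"))
  out <- tibble::tibble(roi = rois, set = set)
  stopifnot(sum(out$set == "RA") + sum(out$set == "N") + sum(out$set == "O") == nrow(a))
  out
}

# Per-node metric values of one node set ("RAbar" = N union O).
set_values <- function(metric_tbl, partition_tbl, set) {
  members <- if (set == "RAbar") {
    partition_tbl$roi[partition_tbl$set != "RA"]
  } else {
    partition_tbl$roi[partition_tbl$set == set]
  }
  metric_tbl$value[metric_tbl$roi %in% members]
}
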