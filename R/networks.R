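# Organelle interaction networks from PCC matrices: serial and differential
# networks, weighted degree of centrality, and first-week-of-change
# detection at a fixed |delta PCC| threshold.

#' Weighted degree of centrality
#'
#' For each node (structure class), the sum of its connection strengths to
#' all other nodes. Strength is |PCC| by default so the degree is
#' non-negative; a signed sum is available.
#'
#' @param matrix symmetric PCC matrix (unit diagonal, ignored).
#' @param signed use signed PCC values instead of absolute.
#' @return named numeric vector of degrees.
#' @examples
#' m <- diag(3); m[1, 2] <- m[2, 1] <- 0.5; m[1, 3] <- m[3, 1] <- -0.5
#' weighted_degree(m)
#' @export
weighted_degree <- function(matrix, signed = FALSE) {
  m <- unclass(as.matrix(matrix))
  diag(m) <- 0
  if (!signed) m <- abs(m)
  rowSums(m, na.rm = TRUE)
}

#' Differential interaction network
#'
#' Element-wise difference of two PCC matrices over the same node set
#' (typically a later week minus week 1); antisymmetric under swapping the
#' arguments.
#'
#' @param week_w,week_1 PCC matrices with identical dimnames.
#' @return difference matrix.
#' @export
delta_network <- function(week_w, week_1) {
  a <- unclass(as.matrix(week_w)); b <- unclass(as.matrix(week_1))
  if (!identical(dim(a), dim(b)) ||
      !identical(dimnames(a), dimnames(b)))
    stop("node sets differ")
  a - b
}

#' First week of significant interaction change
#'
#' For every structure pair, the earliest week w > 1 at which
#' |PCC_w - PCC_1| reaches the threshold (default 0.45), with the signed and
#' absolute change at that week; `NA` for pairs that never cross.
#'
#' @param pcc_by_week named list of PCC matrices, names = week numbers
#'   (must include week 1).
#' @param threshold change threshold on |delta|.
#' @return data.frame: pair nodes, `first_week`, `delta` (signed, at the
#'   first crossing week), `abs_delta`.
#' @export
first_change_week <- function(pcc_by_week, threshold = 0.45) {
  wk <- sort(as.numeric(names(pcc_by_week)))
  if (!1 %in% wk) stop("week-1 matrix is required")
  base <- unclass(as.matrix(pcc_by_week[[as.character(1)]]))
  nodes <- rownames(base)
  pairs <- which(upper.tri(base), arr.ind = TRUE)
  rows <- lapply(seq_len(nrow(pairs)), function(r) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    fw <- NA_real_; del <- NA_real_
    for (w in wk[wk > 1]) {
      d <- unclass(as.matrix(pcc_by_week[[as.character(w)]]))[i, j] -
        base[i, j]
      if (is.finite(d) && abs(d) >= threshold) { fw <- w; del <- d; break }
    }
    data.frame(a = nodes[i], b = nodes[j], first_week = fw,
               delta = del, abs_delta = abs(del))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Centrality time series and relative change
#'
#' Weighted degree per node per week, plus the change relative to week 1.
#'
#' @param pcc_by_week named list of PCC matrices (names = weeks, incl. 1).
#' @param signed passed to [weighted_degree()].
#' @return data.frame: node, week, degree, rel_change.
#' @export
centrality_series <- function(pcc_by_week, signed = FALSE) {
  wk <- sort(as.numeric(names(pcc_by_week)))
  degs <- lapply(wk, function(w)
    weighted_degree(pcc_by_week[[as.character(w)]], signed = signed))
  base <- degs[[which(wk == 1)]]
  rows <- lapply(seq_along(wk), function(i) {
    d <- degs[[i]]
    data.frame(node = names(d), week = wk[i], degree = unname(d),
               rel_change = unname((d - base[names(d)]) /
                                     ifelse(base[names(d)] == 0, NA,
                                            base[names(d)])))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Edge list of an interaction network
#'
#' Serializes a PCC matrix as an edge list (no self-edges) with the signed
#' weight and its absolute value (display width).
#'
#' @param matrix PCC matrix.
#' @param condition optional condition key column.
#' @return data.frame: a, b, pcc, abs_pcc (+ condition).
#' @export
network_edges <- function(matrix, condition = NULL) {
  m <- unclass(as.matrix(matrix))
  idx <- which(upper.tri(m), arr.ind = TRUE)
  out <- data.frame(a = rownames(m)[idx[, 1]], b = colnames(m)[idx[, 2]],
                    pcc = m[idx], abs_pcc = abs(m[idx]))
  if (!is.null(condition)) out$condition <- condition
  out
}
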