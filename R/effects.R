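#' Direct, indirect and total effects of a fitted path model
#'
#' For every ordered latent pair the direct effect is the structural
#' coefficient on the edge (0 when absent) and the indirect effect is the
#' sum, over all directed paths of length two or more, of the product of
#' the edge coefficients along the path -- enumerated explicitly so each
#' contributing path is reported. Total = direct + indirect; because the
#' structural matrix is strictly lower-triangular (nilpotent), the total
#' equals the corresponding entry of `sum_k A^k`.
#'
#' @param fit a `pls_fit`, or a square strictly lower-triangular numeric
#'   matrix of path coefficients (`A[to, from]`).
#' @return An object of class `effects_table`: a data frame with columns
#'   `from`, `to`, `direct`, `indirect`, `total`, with attribute `"paths"`
#'   -- a list of per-path decompositions (`path` string, `value`).
#' @export
effects <- function(fit) {
  A <- if (inherits(fit, "pls_fit")) fit$path_matrix else as.matrix(fit)
  q <- nrow(A)
  if (is.null(rownames(A))) dimnames(A) <- list(seq_len(q), seq_len(q))
  if (any(A[upper.tri(A, diag = TRUE)] != 0))
    stop("path matrix must be strictly lower-triangular (acyclic)")
  nms <- rownames(A)
  rows <- list(); decomp <- list()
  for (src in 1:(q - 1)) {
    for (dst in (src + 1):q) {
      paths <- enumerate_paths(A, src, dst)
      direct <- A[dst, src]
      indirect <- 0
      plist <- list()
      for (pth in paths) {
        val <- prod(A[cbind(pth[-1], pth[-length(pth)])])
        lab <- paste(nms[pth], collapse = " -> ")
        plist[[length(plist) + 1L]] <- data.frame(path = lab, value = val)
        if (length(pth) > 2L) indirect <- indirect + val
      }
      rows[[length(rows) + 1L]] <- data.frame(
        from = nms[src], to = nms[dst],
        direct = direct, indirect = indirect, total = direct + indirect)
      decomp[[paste(nms[src], nms[dst], sep = "->")]] <-
        if (length(plist)) do.call(rbind, plist)
        else data.frame(path = character(0), value = numeric(0))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "paths") <- decomp
  class(out) <- c("effects_table", "data.frame")
  out
}

# All directed paths src -> ... -> dst over nonzero edges of A[to, from].
enumerate_paths <- function(A, src, dst) {
  out <- list()
  walk <- function(node, trail) {
    if (node == dst) { out[[length(out) + 1L]] <<- trail; return(invisible()) }
    for (nxt in which(A[, node] != 0)) {
      if (nxt <= node) next               # lower-triangular: strictly forward
      walk(nxt, c(trail, nxt))
    }
  }
  walk(src, src)
  out
}

#' Total-effects matrix by matrix powers
#'
#' `sum_{k>=1} A^k` for a nilpotent (strictly lower-triangular) coefficient
#' matrix; the closed form `solve(I - A) - I`. Used as the algebraic
#' cross-check of the path-tracing decomposition.
#'
#' @param A strictly lower-triangular numeric matrix (`A[to, from]`).
#' @return Matrix of total effects.
#' @export
total_effects_matrix <- function(A) {
  A <- as.matrix(A)
  if (any(A[upper.tri(A, diag = TRUE)] != 0))
    stop("path matrix must be strictly lower-triangular (acyclic)")
  solve(diag(nrow(A)) - A) - diag(nrow(A))
}
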