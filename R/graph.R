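#' Prior sub-skill relationship graph
#'
#' The six sub-skills form the nodes of a fixed prior graph whose edges
#' encode known associations between sub-skills; the joint model exchanges
#' information only along these edges (plus self-loops). The default edge
#' set is the three pairs hold ratio-hold angle, hold angle-driving
#' smoothness, and hold angle-wrist rotation.
#'
#' @slot adjacency 6 x 6 binary symmetric matrix with unit diagonal, rows and
#'   columns ordered \code{subSkillCodes()}.
#' @slot pairs character matrix (n_edges x 2) of the off-diagonal pairs.
#' @export
setClass("PriorGraph",
  representation(adjacency = "matrix", pairs = "matrix"))

setValidity("PriorGraph", function(object) {
  A <- object@adjacency
  if (!all(dim(A) == c(6L, 6L))) return("adjacency must be 6 x 6")
  if (!identical(rownames(A), subSkillCodes())) return("bad row order")
  if (!all(A %in% c(0, 1))) return("adjacency must be binary")
  if (!isTRUE(all.equal(A, t(A)))) return("adjacency must be symmetric")
  if (!all(diag(A) == 1)) return("self-loops required on every node")
  TRUE
})

#' Build a prior graph from named sub-skill pairs
#'
#' @param pairs list of length-2 character vectors of sub-skill codes, or an
#'   n x 2 character matrix; duplicates are collapsed with a warning,
#'   self-pairs and unknown codes are errors. Defaults to the three known
#'   pairs \code{HR-HA}, \code{HA-DS}, \code{HA-WR}.
#' @return a \code{PriorGraph}. Self-loops are always present, so every
#'   node's allowed attention set is nonempty.
#' @examples
#' priorGraph(defaultPriorPairs())
#' priorGraph(list())  # self-loops only: identity adjacency
#' @export
priorGraph <- function(pairs = defaultPriorPairs()) {
  if (is.matrix(pairs)) pairs <- split(pairs, seq_len(nrow(pairs)))
  codes <- subSkillCodes()
  A <- diag(6L)
  dimnames(A) <- list(codes, codes)
  seen <- character(0)
  kept <- list()
  for (p in pairs) {
    p <- as.character(p)
    if (length(p) != 2L) stop("each pair needs exactly two codes", call. = FALSE)
    checkSubSkillCodes(p)
    if (p[1L] == p[2L])
      stop("self-pair not allowed: ", p[1L], call. = FALSE)
    key <- paste(sort(p), collapse = "-")
    if (key %in% seen) {
      warning("duplicate pair ", key, " collapsed", call. = FALSE)
      next
    }
    seen <- c(seen, key)
    kept[[length(kept) + 1L]] <- sort(p)
    A[p[1L], p[2L]] <- 1
    A[p[2L], p[1L]] <- 1
  }
  pm <- if (length(kept)) do.call(rbind, kept) else
    matrix(character(0), 0L, 2L)
  new("PriorGraph", adjacency = A, pairs = pm)
}

#' @rdname priorGraph
#' @export
defaultPriorPairs <- function() {
  list(c("HR", "HA"), c("HA", "DS"), c("HA", "WR"))
}

#' @rdname priorGraph
#' @param graph a \code{PriorGraph}.
#' @export
adjacency <- function(graph) graph@adjacency

setMethod("show", "PriorGraph", function(object) {
  cat("PriorGraph on", paste(subSkillCodes(), collapse = " "), "\n")
  if (nrow(object@pairs)) {
    cat("  edges:", paste(apply(object@pairs, 1L, paste, collapse = "-"),
                          collapse = ", "), "\n")
  } else cat("  edges: none (self-loops only)\n")
})

#' Masked row-wise softmax over the prior graph
#'
#' Each sub-skill attends only over its allowed set (its prior-graph
#' neighbors and itself): entries where the adjacency is 0 are exactly 0,
#' and each row is a softmax over its allowed entries, so allowed entries
#' lie in [0, 1] and sum to 1 per row.
#'
#' @param scores 6 x 6 matrix of finite attention scores.
#' @param graph a \code{\link{priorGraph}}.
#' @return 6 x 6 attention matrix.
#' @export
maskedAttention <- function(scores, graph) {
  A <- adjacency(graph)
  stopifnot(all(dim(scores) == dim(A)))
  if (!all(is.finite(scores[A == 1])))
    stop("non-finite attention scores on allowed entries", call. = FALSE)
  out <- matrix(0, 6L, 6L, dimnames = dimnames(A))
  for (i in 1:6) {
    allowed <- which(A[i, ] == 1)
    e <- scores[i, allowed]
    e <- exp(e - max(e))
    out[i, allowed] <- e / sum(e)
  }
  out
}
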