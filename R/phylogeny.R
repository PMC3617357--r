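#' Binary lineage ID scheme
#'
#' Every cell carries an ID built from its parent's: daughter \code{i}
#' (1 or 2) of the cell with ID \code{x} gets \code{10 x + i}.  IDs are
#' handled as digit strings: the literal integers overflow 64-bit
#' arithmetic past ~18 divisions while detectable tumors reach division
#' depths near 47.  The root is \code{"1"} and a code of length \code{n}
#' sits at division depth \code{d = n} (the progenitor's birth counts as
#' division 1).
#'
#' @param parentCode lineage code of the parent (character, digits over
#'   \{1, 2\} after the root digit).
#' @param which which daughter, 1 or 2.
#' @return the daughter's lineage code (character).
#' @examples
#' childCode("1", 2)          # "12"
#' nchar(childCode("1", 2))   # = division depth 2
#' @export
childCode <- function(parentCode, which) {
  if (!all(which %in% c(1, 2))) stop("which must be 1 or 2")
  if (!all(grepl("^[12][12]*$", parentCode)))
    stop("parentCode must be a digit sequence over {1, 2}")
  paste0(parentCode, which)
}

# Which-daughter digit for every node (1 for the first-created child).
nodeDigits <- function(parent) {
  n <- length(parent)
  digit <- integer(n)
  seen <- integer(n)
  for (i in seq_len(n)[-1L]) {
    p <- parent[i]
    seen[p] <- seen[p] + 1L
    digit[i] <- seen[p]
  }
  digit
}

#' Lineage codes of tree nodes
#'
#' Reconstructs the digit-string IDs (see \code{\link{childCode}}) for the
#' requested nodes of a \code{\linkS4class{LineageTree}}.
#'
#' @param tree a \code{\linkS4class{LineageTree}}.
#' @param nodes integer node indices (default: all).
#' @return character vector of codes.
#' @export
lineageCode <- function(tree, nodes = seq_along(tree@parent)) {
  digit <- nodeDigits(tree@parent)
  vapply(nodes, function(i) {
    path <- character(0)
    while (i != 0L) {
      path <- c(if (tree@parent[i] == 0L) "1" else as.character(digit[i]),
                path)
      i <- tree@parent[i]
    }
    paste(path, collapse = "")
  }, character(1))
}

#' Construct a lineage tree by hand
#'
#' Builds a validated \code{\linkS4class{LineageTree}} from a parent vector
#' (1-based, root parent 0, children after parents) and an alive flag,
#' computing descendant-in-final-mass counts.  Intended for small fixture
#' and test trees; simulated trees come from
#' \code{\link{simulateClone}(lineage = TRUE)}.
#'
#' @param parent integer parent index per node (root = 0).
#' @param alive logical; is each node part of the final mass?
#' @param d division depth per node; defaults to 1 + depth below the root.
#' @param tBirth,tEvent,gBirth,gEvent,fate,alphaAtEvent,kAtEvent optional
#'   per-node annotations (sensible defaults).
#' @return a \code{\linkS4class{LineageTree}}.
#' @examples
#' tr <- LineageTree(parent = c(0L, 1L, 1L), alive = c(FALSE, TRUE, TRUE))
#' descendantCounts(tr)   # 2, 1, 1
#' @export
LineageTree <- function(parent, alive, d = NULL, tBirth = NULL,
                        tEvent = NULL, gBirth = NULL, gEvent = NULL,
                        fate = NULL, alphaAtEvent = NULL,
                        kAtEvent = NULL) {
  parent <- as.integer(parent)
  n <- length(parent)
  if (is.null(d)) {
    d <- integer(n)
    d[1L] <- 1L
    for (i in seq_len(n)[-1L]) d[i] <- d[parent[i]] + 1L
  }
  if (is.null(tBirth)) tBirth <- as.numeric(d - 1L)
  if (is.null(tEvent)) tEvent <- tBirth + 1
  if (is.null(gBirth)) gBirth <- as.integer(d)
  if (is.null(gEvent)) gEvent <- as.integer(d) + 1L
  if (is.null(fate)) {
    fate <- integer(n)                        # division
    fate[!(seq_len(n) %in% parent)] <- ifelse(alive[!(seq_len(n) %in%
                                                      parent)], 0L, 2L)
    fate[seq_len(n) %in% parent] <- 1L
  }
  if (is.null(alphaAtEvent)) alphaAtEvent <- rep(0, n)
  if (is.null(kAtEvent)) kAtEvent <- rep(0, n)
  cnt <- cpp_descendant_counts(parent, as.logical(alive))
  new("LineageTree", parent = parent, d = as.integer(d),
      gBirth = as.integer(gBirth), gEvent = as.integer(gEvent),
      fate = as.integer(fate), tBirth = as.numeric(tBirth),
      tEvent = as.numeric(tEvent), alphaAtEvent = as.numeric(alphaAtEvent),
      kAtEvent = as.numeric(kAtEvent), alive = as.logical(alive),
      descendantCount = cnt, finalMass = cnt[1L])
}

#' Descendants contributed to the final mass
#'
#' One post-order pass: a node's count is the sum over its children plus
#' one if the node itself is alive in the final mass.  The root's count
#' equals the final mass size.
#'
#' @param tree a \code{\linkS4class{LineageTree}}, or an integer parent
#'   vector (then \code{alive} is required).
#' @param alive logical vector when \code{tree} is a parent vector.
#' @return integer vector of per-node counts.
#' @export
descendantCounts <- function(tree, alive = NULL) {
  if (is(tree, "LineageTree"))
    return(cpp_descendant_counts(tree@parent, tree@alive))
  cpp_descendant_counts(as.integer(tree), as.logical(alive))
}

#' Fractional-mass most recent common ancestor
#'
#' MRCA(\code{x}) is the deepest node whose descendant-in-final-mass count
#' covers at least \code{ceiling(x * finalMass)} of the cells alive at
#' detection; depth ties are broken toward the larger count, then toward
#' the lexicographically smaller lineage code.  MRCA(1) is always the
#' root.  The phenotype is reported at the node's fate event (its division
#' inside the tumor's history).
#'
#' @param tree a \code{\linkS4class{LineageTree}} with non-empty final
#'   mass.
#' @param x mass fraction in (0, 1].
#' @return one-row data.frame: \code{x}, \code{node} (index), \code{code},
#'   \code{d}, \code{g}, \code{alpha}, \code{k},
#'   \code{descendantCount}.
#' @examples
#' tr <- LineageTree(parent = c(0L, 1L, 1L, 2L, 2L, 3L, 3L),
#'                   alive = c(rep(FALSE, 3), rep(TRUE, 4)))
#' mrcaFraction(tr, 1)$d      # 1: the root
#' mrcaFraction(tr, 0.5)$code # "11": tie broken lexicographically
#' @export
mrcaFraction <- function(tree, x) {
  stopifnot(is(tree, "LineageTree"))
  if (length(x) != 1L || !is.finite(x) || x <= 0 || x > 1)
    stop("x must be a single value in (0, 1]")
  cnt <- tree@descendantCount
  N <- tree@finalMass
  if (N < 1L) stop("final mass is empty")
  m <- as.integer(ceiling(x * N))
  cand <- which(cnt >= m)
  dmax <- max(tree@d[cand])
  cand <- cand[tree@d[cand] == dmax]
  if (length(cand) > 1L) {
    cmax <- max(cnt[cand])
    cand <- cand[cnt[cand] == cmax]
    if (length(cand) > 1L)
      cand <- cand[order(lineageCode(tree, cand))][1L]
  }
  i <- cand[1L]
  data.frame(x = x, node = i, code = lineageCode(tree, i), d = tree@d[i],
             g = tree@gEvent[i], alpha = tree@alphaAtEvent[i],
             k = tree@kAtEvent[i], descendantCount = cnt[i],
             stringsAsFactors = FALSE)
}

#' MRCA phenotypes across a set of mass fractions
#'
#' @param tree a \code{\linkS4class{LineageTree}}.
#' @param x vector of mass fractions.
#' @return data.frame with one row per fraction (see
#'   \code{\link{mrcaFraction}}).
#' @export
mrcaPhenotypes <- function(tree, x = c(1, 0.999, 0.995, 0.99, 0.95, 0.90,
                                       0.80, 0.70, 0.60, 0.50)) {
  do.call(rbind, lapply(x, function(xx) mrcaFraction(tree, xx)))
}

#' Newick export of a lineage tree
#'
#' Serializes a (modest-sized) lineage tree to Newick text.  Node labels
#' are the lineage codes, branch lengths are cell lifespans in days, and
#' optional bracketed comments carry the phenotype snapshot at the fate
#' event.  Intended for trees of up to ~10^5 nodes (e.g. normal clones or
#' pruned tumor ancestries), not full 10^6-cell tumors.
#'
#' @param tree a \code{\linkS4class{LineageTree}}.
#' @param annotate attach \code{[&d=..,g=..,k=..,alpha=..]} comments.
#' @return a single Newick string (terminated by \code{";"}).
#' @examples
#' tr <- LineageTree(parent = c(0L, 1L, 1L), alive = c(FALSE, TRUE, TRUE))
#' asNewick(tr)   # "(11:30,12:30)1:30;" (default 1-month lifespans)
#' @export
asNewick <- function(tree, annotate = FALSE) {
  stopifnot(is(tree, "LineageTree"))
  n <- length(tree@parent)
  codes <- lineageCode(tree)
  children <- split(seq_len(n)[-1L], tree@parent[-1L])
  len <- (tree@tEvent - tree@tBirth) * 30
  note <- if (annotate)
    sprintf("[&d=%d,g=%d,k=%.6g,alpha=%.6g]", tree@d, tree@gEvent,
            tree@kAtEvent, tree@alphaAtEvent)
  else rep("", n)
  build <- function(i) {
    kids <- children[[as.character(i)]]
    lab <- paste0(codes[i], note[i], ":", format(len[i], digits = 10))
    if (is.null(kids)) return(lab)
    paste0("(", paste(vapply(kids, build, character(1)), collapse = ","),
           ")", lab)
  }
  paste0(build(1L), ";")
}
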