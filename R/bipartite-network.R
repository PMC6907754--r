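#' Weighted bipartite plant-pollinator network
#'
#' Construct a weighted bipartite network from a long table of interaction
#' strengths. Rows of the underlying matrix are plant species, columns are
#' pollinator species (morphotypes; bee sexes may appear as distinct labels),
#' and each cell \eqn{a_{ij} \ge 0} is the interaction strength of plant
#' \eqn{i} with pollinator \eqn{j} under either the encounter-based or the
#' visit-based measure.
#'
#' Zero-strength cells are treated as absent links: they are dropped on
#' construction, and any species left without a single positive link is
#' removed. Rows and columns are sorted by descending marginal total
#' (alphabetical tie-break), the ordering weighted NODF requires; all other
#' descriptors are permutation-invariant so the sorting is harmless.
#'
#' @param cells data frame with columns `plant`, `pollinator`, `strength`.
#'   Duplicate (plant, pollinator) rows are summed.
#' @param measure `"encounter"` or `"visit"`; which strength measure the
#'   weights represent.
#' @return An object of class `bipartite_network`: a list with elements
#'   `W` (the plants x pollinators strength matrix, with dimnames) and
#'   `measure`.
#' @examples
#' cells <- data.frame(plant = c("p1", "p1", "p2"),
#'                     pollinator = c("z1", "z2", "z1"),
#'                     strength = c(2, 2, 1))
#' net <- bipartite_network(cells, measure = "encounter")
#' net
#' @export
bipartite_network <- function(cells, measure = c("encounter", "visit")) {
  measure <- match.arg(measure)
  stopifnot(is.data.frame(cells))
  req <- c("plant", "pollinator", "strength")
  missing_cols <- setdiff(req, names(cells))
  if (length(missing_cols) > 0L) {
    stop("cells is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(cells) == 0L) stop("cells is empty: cannot build a network", call. = FALSE)
  if (any(!is.finite(cells$strength))) {
    stop("non-finite strength values", call. = FALSE)
  }
  if (any(cells$strength < 0)) {
    bad <- which(cells$strength < 0)[1L]
    stop(sprintf("negative interaction strength at row %d (%s, %s)",
                 bad, cells$plant[bad], cells$pollinator[bad]), call. = FALSE)
  }
  cells$plant <- as.character(cells$plant)
  cells$pollinator <- as.character(cells$pollinator)
  if (any(!nzchar(cells$plant)) || any(!nzchar(cells$pollinator))) {
    stop("empty species labels are not allowed", call. = FALSE)
  }
  cells <- cells[cells$strength > 0, , drop = FALSE]
  if (nrow(cells) == 0L) {
    stop("no positive-strength cells: cannot build a network", call. = FALSE)
  }
  agg <- stats::aggregate(strength ~ plant + pollinator, data = cells, FUN = sum)
  W <- stats::xtabs(strength ~ plant + pollinator, data = agg)
  W <- matrix(as.numeric(W), nrow = nrow(W), dimnames = dimnames(W))
  names(dimnames(W)) <- NULL
  new_bipartite_network(W, measure)
}

# low-level constructor from an already-built matrix; drops empty margins
# and applies the canonical sort
new_bipartite_network <- function(W, measure) {
  stopifnot(is.matrix(W), all(W >= 0))
  W <- W[rowSums(W) > 0, colSums(W) > 0, drop = FALSE]
  if (nrow(W) == 0L || ncol(W) == 0L) {
    stop("network has no species with positive strength", call. = FALSE)
  }
  W <- sort_network_matrix(W)
  structure(list(W = W, measure = measure), class = "bipartite_network")
}

# descending marginal totals, alphabetical tie-break
sort_network_matrix <- function(W) {
  ro <- order(-rowSums(W), rownames(W))
  co <- order(-colSums(W), colnames(W))
  W[ro, co, drop = FALSE]
}

#' @export
print.bipartite_network <- function(x, ...) {
  cat(sprintf("Weighted bipartite network (%s-based strength)\n", x$measure))
  cat(sprintf("  %d plants x %d pollinators, %d links, total strength %.4g\n",
              nrow(x$W), ncol(x$W), sum(x$W > 0), sum(x$W)))
  invisible(x)
}

#' @export
summary.bipartite_network <- function(object, ...) {
  W <- object$W
  s <- W[W > 0]
  out <- list(
    measure = object$measure,
    n_plants = nrow(W), n_pollinators = ncol(W),
    n_links = length(s), total = sum(s),
    connectance = length(s) / length(W),
    strength_quartiles = stats::quantile(s, c(0, .25, .5, .75, 1))
  )
  class(out) <- "summary.bipartite_network"
  out
}

#' @export
print.summary.bipartite_network <- function(x, ...) {
  cat(sprintf("%s-based network: %d plants, %d pollinators, %d links (connectance %.3f)\n",
              x$measure, x$n_plants, x$n_pollinators, x$n_links, x$connectance))
  cat("link strength quartiles:\n")
  print(signif(x$strength_quartiles, 4))
  invisible(x)
}

#' Species labels of a network
#'
#' @param network a `bipartite_network`
#' @return character vector of plant or pollinator labels, in matrix order.
#' @export
plants <- function(network) rownames(network$W)

#' @rdname plants
#' @export
pollinators <- function(network) colnames(network$W)

#' Long-format view of a network's links
#'
#' @param network a `bipartite_network`
#' @return data frame with columns `plant`, `pollinator`, `strength`, one
#'   row per positive cell.
#' @export
network_cells <- function(network) {
  W <- network$W
  idx <- which(W > 0, arr.ind = TRUE)
  out <- data.frame(
    plant = rownames(W)[idx[, 1]],
    pollinator = colnames(W)[idx[, 2]],
    strength = W[idx],
    stringsAsFactors = FALSE
  )
  out <- out[order(out$plant, out$pollinator), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Keep only a given set of links
#'
#' Restricts a network to the (plant, pollinator) pairs listed, dropping any
#' species left without links. Used to put the encounter-based network on the
#' same link set as the visit-based one after imputation exclusions.
#'
#' @param network a `bipartite_network`
#' @param pairs data frame with columns `plant` and `pollinator`
#' @return a `bipartite_network` with the same measure tag.
#' @export
filter_links <- function(network, pairs) {
  stopifnot(all(c("plant", "pollinator") %in% names(pairs)))
  W <- network$W
  keep <- matrix(FALSE, nrow(W), ncol(W), dimnames = dimnames(W))
  ok <- pairs$plant %in% rownames(W) & pairs$pollinator %in% colnames(W)
  keep[cbind(pairs$plant[ok], pairs$pollinator[ok])] <- TRUE
  W[!keep] <- 0
  new_bipartite_network(W, network$measure)
}

#' Barplot of interaction strengths
#'
#' A simple diagnostic plot: sorted link strengths on a log axis, showing the
#' characteristic few-strong / many-weak shape of pollination networks.
#'
#' @param x a `bipartite_network`
#' @param ... passed to [graphics::barplot()]
#' @export
plot.bipartite_network <- function(x, ...) {
  s <- sort(x$W[x$W > 0], decreasing = TRUE)
  graphics::barplot(s, log = "y", border = NA, names.arg = FALSE,
                    xlab = "link rank", ylab = "interaction strength",
                    main = sprintf("%s-based link strengths", x$measure), ...)
  invisible(x)
}
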