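#' Weighted NODF nestedness
#'
#' With rows and columns sorted by descending marginal totals, each ordered
#' row pair (u above v) scores
#' \deqn{100 \cdot \frac{|\{c : 0 < a_{vc} < a_{uc}\}|}{|\{c : a_{vc} > 0\}|}}
#' provided the marginal totals decrease strictly (\eqn{A_u > A_v});
#' pairs with tied totals score 0, which makes tie-breaking in the sort
#' inconsequential. Column pairs are scored the same way with roles
#' transposed. The index is the mean score over all row pairs and all column
#' pairs, ranging 0-100.
#'
#' Two dialects of the index are in circulation and differ on matrices that
#' are not strongly nested: the defining formula above sorts and gates pairs
#' by marginal totals (`dialect = "marginal"`, the default), whereas the
#' `vegan`/`bipartite` implementations sort and gate by fill — the number of
#' nonzero cells per line, with marginal totals only as tie-break
#' (`dialect = "fill"`). The fill dialect is provided for calibration
#' against results computed with those packages.
#'
#' @param network a [bipartite_network()] (re-sorted internally)
#' @param dialect `"marginal"` (defining formula) or `"fill"`
#'   (vegan/bipartite convention)
#' @return weighted NODF in \[0, 100\].
#' @export
weighted_nodf <- function(network, dialect = c("marginal", "fill")) {
  dialect <- match.arg(dialect)
  W <- network$W
  if (nrow(W) < 2L && ncol(W) < 2L) {
    stop("weighted NODF undefined: need at least 2 rows or 2 columns",
         call. = FALSE)
  }
  if (dialect == "marginal") {
    W <- sort_network_matrix(W)
    r_key <- rowSums(W)
    c_key <- colSums(W)
  } else {
    ro <- order(rowSums(W > 0), rowSums(W), decreasing = TRUE)
    co <- order(colSums(W > 0), colSums(W), decreasing = TRUE)
    W <- W[ro, co, drop = FALSE]
    r_key <- rowSums(W > 0)
    c_key <- colSums(W > 0)
  }
  rows <- nodf_pair_scores(W, r_key)
  cols <- nodf_pair_scores(t(W), c_key)
  (rows[1] + cols[1]) / (rows[2] + cols[2])
}

# score all ordered row pairs of M; a pair counts only when the upper line's
# key strictly exceeds the lower's ("decreasing fill")
nodf_pair_scores <- function(M, key) {
  n <- nrow(M)
  if (n < 2L) return(c(0, 0))
  nz <- rowSums(M > 0)
  s <- 0
  for (v in 2:n) {
    u <- 1:(v - 1L)
    eligible <- key[u] > key[v]
    if (!any(eligible)) next
    below <- M[v, ]
    # cells of the poorer row that are positive yet smaller than the richer
    # row's corresponding cells
    cmp <- sweep(M[u, , drop = FALSE], 2, below, ">") &
      rep(below > 0, each = length(u))
    s <- s + sum(100 * rowSums(cmp)[eligible] / nz[v])
  }
  c(s, n * (n - 1) / 2)
}

#' H2' network-level specialization
#'
#' Standardized two-dimensional Shannon entropy of the interaction weights.
#' With \eqn{p_{ij} = a_{ij}/m}, \eqn{H_2 = -\sum p_{ij} \ln p_{ij}} is
#' compared against the extremes attainable with the observed marginal
#' totals: \eqn{H_{2max}}, the entropy of the independent outer-product
#' allocation \eqn{\hat a_{ij} = A_i A_j / m} (equivalently the sum of the
#' two marginal entropies), and \eqn{H_{2min}}, the entropy of a greedy
#' concentration allocation that repeatedly places
#' \eqn{\min(A_i^{rem}, A_j^{rem})} in the cell of the currently largest
#' remaining row and column totals. Both extremes use continuous marginals,
#' consistent with real-valued abundance-weighted strengths. Then
#' \deqn{H_2' = \frac{H_{2max} - H_2}{H_{2max} - H_{2min}},}
#' clamped to \[0, 1\]: 0 is maximal generalization (interactions
#' proportional to partner availability), 1 maximal specialization.
#'
#' @param network a [bipartite_network()]
#' @return H2' in \[0, 1\].
#' @export
h2_prime <- function(network) {
  W <- network$W
  m <- sum(W)
  h2 <- shannon_entropy(W / m)
  h2max <- shannon_entropy(rowSums(W) / m) + shannon_entropy(colSums(W) / m)
  h2min <- greedy_min_entropy(rowSums(W), colSums(W))
  if (h2max - h2min < 1e-12) {
    stop("H2' undefined: degenerate marginals", call. = FALSE)
  }
  min(max((h2max - h2) / (h2max - h2min), 0), 1)
}

shannon_entropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

# entropy of the greedy concentration allocation of mass consistent with the
# given row/column totals (continuous analogue of packing interactions into
# as few cells as possible)
greedy_min_entropy <- function(r, c) {
  m <- sum(r)
  tol <- 1e-12 * m
  h <- 0
  while (TRUE) {
    i <- which.max(r)
    j <- which.max(c)
    v <- min(r[i], c[j])
    if (v <= tol) break
    p <- v / m
    h <- h - p * log(p)
    r[i] <- r[i] - v
    c[j] <- c[j] - v
  }
  h
}

#' Interaction evenness
#'
#' Shannon entropy of the normalized interaction weights divided by its
#' maximum: \eqn{IE = H_2 / \ln(R \cdot C)} for an \eqn{R \times C} network,
#' following the definition over all potential links. The variant dividing
#' by the number of realized links is available via `denominator =
#' "realized"`.
#'
#' @param network a [bipartite_network()]
#' @param denominator `"potential"` (default, \eqn{\ln(RC)}) or
#'   `"realized"` (\eqn{\ln} number of links)
#' @return evenness in \[0, 1\].
#' @export
interaction_evenness <- function(network,
                                 denominator = c("potential", "realized")) {
  denominator <- match.arg(denominator)
  W <- network$W
  n_cells <- switch(denominator,
                    potential = length(W),
                    realized = sum(W > 0))
  if (n_cells <= 1L) {
    stop("interaction evenness undefined for a single-cell network",
         call. = FALSE)
  }
  shannon_entropy(W / sum(W)) / log(n_cells)
}

#' Generality (weighted mean effective number of partners)
#'
#' For each species of the focal level, the effective number of partners is
#' the exponential Shannon entropy of its partner-use distribution,
#' \eqn{n_i = \exp(-\sum_j (a_{ij}/A_i)\ln(a_{ij}/A_i))}. Generality is the
#' marginal-weighted mean \eqn{\sum_i (A_i/m)\, n_i}: plant generality is
#' the weighted mean number of pollinator species per plant species
#' (equivalent to vulnerability in food webs), and conversely for
#' pollinators.
#'
#' @param network a [bipartite_network()]
#' @param level `"plant"` or `"pollinator"`
#' @return generality, between 1 and the size of the opposite level.
#' @export
generality <- function(network, level = c("plant", "pollinator")) {
  level <- match.arg(level)
  W <- network$W
  if (level == "pollinator") W <- t(W)
  A <- rowSums(W)
  n_eff <- apply(W / A, 1, function(p) exp(shannon_entropy(p)))
  sum(A / sum(A) * n_eff)
}

#' All network descriptors for one network
#'
#' @param network a [bipartite_network()]
#' @param ie_denominator passed to [interaction_evenness()]
#' @param wnodf_dialect passed to [weighted_nodf()]
#' @return one-row data frame: `measure`, `wnodf`, `h2_prime`,
#'   `interaction_evenness`, `plant_generality`, `pollinator_generality`.
#' @export
network_metrics <- function(network, ie_denominator = "potential",
                            wnodf_dialect = "marginal") {
  data.frame(
    measure = network$measure,
    wnodf = weighted_nodf(network, wnodf_dialect),
    h2_prime = h2_prime(network),
    interaction_evenness = interaction_evenness(network, ie_denominator),
    plant_generality = generality(network, "plant"),
    pollinator_generality = generality(network, "pollinator"),
    stringsAsFactors = FALSE
  )
}
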