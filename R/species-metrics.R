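#' Species strength
#'
#' The strength of a species is the sum, over its interaction partners, of
#' the partners' dependence on it. With \eqn{a_{ij}} the link strengths,
#' row totals \eqn{A_i} and column totals \eqn{A_j}, a pollinator's strength
#' is \eqn{S_j = \sum_i a_{ij}/A_i} and a plant's is
#' \eqn{S_i = \sum_j a_{ij}/A_j}. Because every species' dependences sum to
#' one, the strengths of one trophic level sum exactly to the number of
#' species on the opposite level.
#'
#' @param network a [bipartite_network()]
#' @param level `"plant"` or `"pollinator"`: whose strengths to return
#' @return named numeric vector of strengths.
#' @export
species_strength <- function(network, level = c("plant", "pollinator")) {
  level <- match.arg(level)
  W <- network$W
  if (level == "plant") {
    # dependence of each pollinator on the plant, summed over pollinators
    rowSums(sweep(W, 2, colSums(W), "/"))
  } else {
    colSums(W / rowSums(W))
  }
}

#' Push-pull index of interaction asymmetry
#'
#' For focal species \eqn{i} with \eqn{k_i} partners, the push-pull index is
#' the mean per-partner difference between the partner's dependence on the
#' focal species and the focal species' dependence on the partner:
#' \deqn{PP_i = \frac{1}{k_i}\sum_{j \in partners(i)} (d_{ji} - d_{ij}),}
#' with \eqn{d_{ij} = a_{ij}/A_i}. It ranges from -1 to 1; positive values
#' mark "pushers" (species affecting their partners more strongly than they
#' are affected), negative values "pullers".
#'
#' @inheritParams species_strength
#' @param summed if `TRUE`, return the summed rather than mean asymmetry
#'   (a sensitivity variant; it is no longer bounded by \[-1, 1\]).
#' @return named numeric vector of index values.
#' @export
push_pull <- function(network, level = c("plant", "pollinator"), summed = FALSE) {
  level <- match.arg(level)
  W <- network$W
  dep_on_partner_rows <- W / rowSums(W)              # d_{ij}: plant i on pollinator j
  dep_on_partner_cols <- sweep(W, 2, colSums(W), "/") # d_{ji}: pollinator j on plant i
  present <- W > 0
  if (level == "plant") {
    diff <- (dep_on_partner_cols - dep_on_partner_rows) * present
    tot <- rowSums(diff)
    k <- rowSums(present)
  } else {
    diff <- (dep_on_partner_rows - dep_on_partner_cols) * present
    tot <- colSums(diff)
    k <- colSums(present)
  }
  if (summed) tot else tot / k
}

#' d' standardized species-level specialization
#'
#' Kullback-Leibler divergence between a species' partner-use distribution
#' \eqn{p'_{ij} = a_{ij}/A_i} and partner availability \eqn{q_j = A_j/m},
#' standardized to \[0, 1\]:
#' \deqn{d_i = \sum_j p'_{ij}\,\ln(p'_{ij}/q_j), \qquad
#'       d'_i = \frac{d_i - d_{min}}{d_{max} - d_{min}}}
#' with \eqn{d_{max} = \ln(m/A_i)} (attained by exclusive use of a partner
#' whose whole total comes from the focal species) and, because strengths
#' here are continuous abundance-weighted reals rather than integer counts,
#' the continuous-limit minimum \eqn{d_{min} = 0} (use proportional to
#' availability). Values are clamped to \[0, 1\] against floating-point
#' spill. 0 means maximal generalization, 1 maximal specialization.
#'
#' If a species holds the entire opposite level (degenerate
#' \eqn{d_{max} = 0}), its d' is defined as 0 and a message is emitted.
#'
#' @inheritParams species_strength
#' @return named numeric vector of d' values in \[0, 1\].
#' @export
d_prime <- function(network, level = c("plant", "pollinator")) {
  level <- match.arg(level)
  W <- network$W
  if (level == "pollinator") W <- t(W)
  m <- sum(W)
  A <- rowSums(W)
  q <- colSums(W) / m
  P <- W / A
  terms <- P * log(sweep(P, 2, q, "/"))
  terms[W == 0] <- 0  # 0 * log(0/q) contributes nothing
  d_raw <- rowSums(terms)
  d_max <- log(m / A)
  degenerate <- d_max <= 0
  if (any(degenerate)) {
    message("d': species holding the whole opposite level, d' set to 0 for: ",
            paste(rownames(W)[degenerate], collapse = ", "))
  }
  out <- ifelse(degenerate, 0, pmin(pmax(d_raw / ifelse(degenerate, 1, d_max), 0), 1))
  stats::setNames(out, rownames(W))
}

#' All species descriptors for one network
#'
#' @param network a [bipartite_network()]
#' @return data frame with one row per species: `species`, `level`,
#'   `degree`, `strength`, `push_pull`, `d_prime`.
#' @export
species_metrics <- function(network) {
  W <- network$W
  out <- rbind(
    data.frame(species = rownames(W), level = "plant",
               degree = rowSums(W > 0),
               strength = species_strength(network, "plant"),
               push_pull = push_pull(network, "plant"),
               d_prime = d_prime(network, "plant"),
               stringsAsFactors = FALSE),
    data.frame(species = colnames(W), level = "pollinator",
               degree = colSums(W > 0),
               strength = species_strength(network, "pollinator"),
               push_pull = push_pull(network, "pollinator"),
               d_prime = d_prime(network, "pollinator"),
               stringsAsFactors = FALSE)
  )
  rownames(out) <- NULL
  out
}
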