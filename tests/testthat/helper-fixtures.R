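# Shared fixtures and independent oracles, built in code.

toy_cells <- function() {
  # W = [[2, 2], [1, 0]] with rows p1, p2 and columns z1, z2
  data.frame(plant = c("p1", "p1", "p2"),
             pollinator = c("z1", "z2", "z1"),
             strength = c(2, 2, 1),
             stringsAsFactors = FALSE)
}

toy_network <- function(measure = "encounter") {
  bipartite_network(toy_cells(), measure = measure)
}

# random integer matrix with no empty row or column
random_integer_matrix <- function(nr, nc, max_val = 5) {
  repeat {
    W <- matrix(sample(0:max_val, nr * nc, replace = TRUE), nr, nc)
    if (all(rowSums(W) > 0) && all(colSums(W) > 0)) break
  }
  dimnames(W) <- list(sprintf("p%02d", seq_len(nr)), sprintf("z%02d", seq_len(nc)))
  W
}

network_from_matrix <- function(W, measure = "encounter", dimnames = NULL) {
  if (!is.null(dimnames)) dimnames(W) <- dimnames
  if (is.null(rownames(W))) rownames(W) <- sprintf("p%02d", seq_len(nrow(W)))
  if (is.null(colnames(W))) colnames(W) <- sprintf("z%02d", seq_len(ncol(W)))
  idx <- which(W > 0, arr.ind = TRUE)
  bipartite_network(data.frame(plant = rownames(W)[idx[, 1]],
                               pollinator = colnames(W)[idx[, 2]],
                               strength = W[idx],
                               stringsAsFactors = FALSE),
                    measure = measure)
}

# --- independent oracles -----------------------------------------------------

# species strength / push-pull straight from the dependence definitions,
# cell by cell
oracle_species_metrics <- function(W) {
  A_r <- rowSums(W); A_c <- colSums(W)
  s_plant <- pp_plant <- numeric(nrow(W))
  for (i in seq_len(nrow(W))) {
    deps <- asym <- 0; k <- 0
    for (j in seq_len(ncol(W))) {
      if (W[i, j] > 0) {
        deps <- deps + W[i, j] / A_c[j]
        asym <- asym + (W[i, j] / A_c[j] - W[i, j] / A_r[i])
        k <- k + 1
      }
    }
    s_plant[i] <- deps; pp_plant[i] <- asym / k
  }
  s_poll <- pp_poll <- numeric(ncol(W))
  for (j in seq_len(ncol(W))) {
    deps <- asym <- 0; k <- 0
    for (i in seq_len(nrow(W))) {
      if (W[i, j] > 0) {
        deps <- deps + W[i, j] / A_r[i]
        asym <- asym + (W[i, j] / A_r[i] - W[i, j] / A_c[j])
        k <- k + 1
      }
    }
    s_poll[j] <- deps; pp_poll[j] <- asym / k
  }
  list(strength_plant = s_plant, strength_pollinator = s_poll,
       push_pull_plant = pp_plant, push_pull_pollinator = pp_poll)
}

# weighted NODF by direct enumeration of every ordered row and column pair
oracle_wnodf <- function(W) {
  score_pairs <- function(M) {
    tot <- rowSums(M)
    s <- 0; n_pairs <- 0
    n <- nrow(M)
    for (u in seq_len(n - 1)) {
      for (v in (u + 1):n) {
        n_pairs <- n_pairs + 1
        if (tot[u] > tot[v]) {
          nz <- sum(M[v, ] > 0)
          hit <- sum(M[v, ] > 0 & M[v, ] < M[u, ])
          s <- s + 100 * hit / nz
        }
      }
    }
    c(s, n_pairs)
  }
  ro <- order(-rowSums(W), rownames(W))
  co <- order(-colSums(W), colnames(W))
  W <- W[ro, co, drop = FALSE]
  r <- score_pairs(W)
  c2 <- score_pairs(t(W))
  (r[1] + c2[1]) / (r[2] + c2[2])
}

# tiny survey fixture with hand-checkable weekly arithmetic
tiny_survey <- function() {
  encounters <- data.frame(
    week = c(1, 1, 2, 1),
    plant = c("A", "A", "A", "B"),
    pollinator = c("x", "x", "x", "y"),
    stringsAsFactors = FALSE)
  flowers <- data.frame(
    week = c(1, 2, 1),
    plant = c("A", "A", "B"),
    flowers_surveyed = c(40, 20, 10),
    flower_abundance = c(10, 5, 2),
    stringsAsFactors = FALSE)
  visits <- data.frame(
    plant = c("A", "A", "A", "B"),
    pollinator = c("x", "x", "x", "y"),
    n_visits = c(3, 5, 4, 2),
    stringsAsFactors = FALSE)
  list(encounters = encounters, flowers = flowers, visits = visits)
}

write_survey_csvs <- function(surv, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  paths <- list(encounters = file.path(dir, "encounters.csv"),
                flowers = file.path(dir, "flowers.csv"),
                visits = file.path(dir, "visits.csv"))
  write.csv(surv$encounters, paths$encounters, row.names = FALSE)
  write.csv(surv$flowers, paths$flowers, row.names = FALSE)
  write.csv(surv$visits, paths$visits, row.names = FALSE)
  paths
}
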