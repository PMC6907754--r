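#' Weekly encounter frequencies
#'
#' For every (week, plant, pollinator) with at least one encounter, the
#' encounter frequency is the number of encounters observed that week divided
#' by the number of open flowers surveyed on that plant species that week.
#' Weeks in which a pair was not observed yield no record.
#'
#' @param encounters data frame `week, plant, pollinator` (one row per
#'   encounter event)
#' @param flower_surveys data frame `week, plant, flowers_surveyed,
#'   flower_abundance`
#' @return data frame `week, plant, pollinator, frequency`.
#' @export
weekly_encounter_frequency <- function(encounters, flower_surveys) {
  stopifnot(all(c("week", "plant", "pollinator") %in% names(encounters)),
            all(c("week", "plant", "flowers_surveyed") %in% names(flower_surveys)))
  if (nrow(encounters) == 0L) {
    return(data.frame(week = integer(0), plant = character(0),
                      pollinator = character(0), frequency = numeric(0)))
  }
  counts <- stats::aggregate(
    list(n = rep(1L, nrow(encounters))),
    by = encounters[c("week", "plant", "pollinator")], FUN = sum)
  key <- function(w, p) paste(w, p, sep = "\r")
  fs <- flower_surveys$flowers_surveyed[
    match(key(counts$week, counts$plant),
          key(flower_surveys$week, flower_surveys$plant))]
  bad <- is.na(fs) | fs <= 0
  if (any(bad)) {
    off <- unique(paste0("(week ", counts$week[bad], ", ", counts$plant[bad], ")"))
    stop("encounters recorded with no positive flowers_surveyed for: ",
         paste(off, collapse = ", "), call. = FALSE)
  }
  out <- counts[c("week", "plant", "pollinator")]
  out$frequency <- counts$n / fs
  out <- out[order(out$week, out$plant, out$pollinator), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Encounter-based interaction strength
#'
#' The encounter-based strength of the link between plant \eqn{i} and
#' pollinator \eqn{j} is the sum over survey weeks of the weekly encounter
#' frequency multiplied by the weekly flower abundance of the plant:
#' \deqn{a_{ij} = \sum_w \mathrm{freq}_{wij} \cdot \mathrm{abund}_{wi}.}
#' Weighting by flower abundance corrects for sampling effort not being
#' proportional to how many flowers a species actually offers.
#'
#' @inheritParams weekly_encounter_frequency
#' @param weekly_frequencies output of [weekly_encounter_frequency()]
#' @return a [bipartite_network()] with `measure = "encounter"`.
#' @export
encounter_strength <- function(weekly_frequencies, flower_surveys) {
  stopifnot(all(c("week", "plant", "pollinator", "frequency") %in%
                  names(weekly_frequencies)),
            all(c("week", "plant", "flower_abundance") %in% names(flower_surveys)))
  wf <- weekly_frequencies
  key <- function(w, p) paste(w, p, sep = "\r")
  ab <- flower_surveys$flower_abundance[
    match(key(wf$week, wf$plant), key(flower_surveys$week, flower_surveys$plant))]
  if (any(is.na(ab))) {
    bad <- is.na(ab)
    off <- unique(paste0("(week ", wf$week[bad], ", ", wf$plant[bad], ")"))
    stop("missing flower_abundance for: ", paste(off, collapse = ", "),
         call. = FALSE)
  }
  contrib <- data.frame(plant = wf$plant, pollinator = wf$pollinator,
                        strength = wf$frequency * ab,
                        stringsAsFactors = FALSE)
  bipartite_network(contrib, measure = "encounter")
}

#' Estimate mean visits per encounter for every interaction
#'
#' Resolves, for each (plant, pollinator) interaction present in the
#' encounter network, a mean number of flowers visited per encounter, in
#' priority order:
#' \enumerate{
#'   \item own follow observations: the arithmetic mean of all
#'     `n_visits` samples for the pair (pooled over years), provenance
#'     `"observed"`;
#'   \item a configured donor — a functionally similar pollinator with an
#'     observed estimate on the same plant — whose mean is borrowed,
#'     provenance `"donor"`;
#'   \item a configured expert default value, provenance `"expert"`;
#'   \item otherwise the interaction is marked `"excluded"` (`mean_visits`
#'     `NA`) and is dropped from all downstream analyses.
#' }
#'
#' @param visit_samples data frame `plant, pollinator, n_visits` (one row per
#'   4-minute follow, `n_visits >= 1`)
#' @param interactions data frame `plant, pollinator`: the link set of the
#'   encounter network (e.g. `network_cells(net)`)
#' @param donors optional data frame `plant, pollinator, donor_pollinator`
#' @param expert_defaults optional data frame `plant, pollinator, mean_visits`
#' @return data frame `plant, pollinator, mean_visits, n_obs, provenance`
#'   with one row per interaction; attribute `"provenance_counts"` holds the
#'   per-class tally and the count of observed estimates based on at least 5
#'   follows (a reliability diagnostic, not a filter).
#' @export
estimate_visits <- function(visit_samples, interactions,
                            donors = NULL, expert_defaults = NULL) {
  stopifnot(all(c("plant", "pollinator", "n_visits") %in% names(visit_samples)),
            all(c("plant", "pollinator") %in% names(interactions)))
  if (any(visit_samples$n_visits < 1)) {
    stop("visit samples violate n_visits >= 1", call. = FALSE)
  }
  pairs <- unique(interactions[c("plant", "pollinator")])
  pkey <- function(p, z) paste(p, z, sep = "\r")

  means <- n_obs <- numeric(0)
  if (nrow(visit_samples) > 0L) {
    agg <- stats::aggregate(n_visits ~ plant + pollinator, data = visit_samples,
                            FUN = mean)
    cnt <- stats::aggregate(list(n = rep(1L, nrow(visit_samples))),
                            by = visit_samples[c("plant", "pollinator")],
                            FUN = sum)
    means <- stats::setNames(agg$n_visits, pkey(agg$plant, agg$pollinator))
    n_obs <- stats::setNames(cnt$n, pkey(cnt$plant, cnt$pollinator))
  }
  donor_map <- character(0)
  if (!is.null(donors) && nrow(donors) > 0L) {
    bad <- !pkey(donors$plant, donors$donor_pollinator) %in% names(means)
    if (any(bad)) {
      stop("donor pollinator(s) without an observed visit estimate on the same plant: ",
           paste(unique(paste0("(", donors$plant[bad], ", ",
                               donors$donor_pollinator[bad], ")")),
                 collapse = ", "), call. = FALSE)
    }
    donor_map <- stats::setNames(donors$donor_pollinator,
                                 pkey(donors$plant, donors$pollinator))
  }
  expert_map <- numeric(0)
  if (!is.null(expert_defaults) && nrow(expert_defaults) > 0L) {
    expert_map <- stats::setNames(expert_defaults$mean_visits,
                                  pkey(expert_defaults$plant,
                                       expert_defaults$pollinator))
  }

  k <- pkey(pairs$plant, pairs$pollinator)
  mean_visits <- rep(NA_real_, nrow(pairs))
  nobs <- integer(nrow(pairs))
  prov <- character(nrow(pairs))
  for (r in seq_len(nrow(pairs))) {
    if (k[r] %in% names(means)) {
      mean_visits[r] <- means[[k[r]]]
      nobs[r] <- n_obs[[k[r]]]
      prov[r] <- "observed"
    } else if (k[r] %in% names(donor_map)) {
      dk <- pkey(pairs$plant[r], donor_map[[k[r]]])
      mean_visits[r] <- means[[dk]]
      prov[r] <- "donor"
    } else if (k[r] %in% names(expert_map)) {
      mean_visits[r] <- expert_map[[k[r]]]
      prov[r] <- "expert"
    } else {
      prov[r] <- "excluded"
    }
  }
  out <- data.frame(plant = pairs$plant, pollinator = pairs$pollinator,
                    mean_visits = mean_visits, n_obs = nobs,
                    provenance = factor(prov, levels = c("observed", "donor",
                                                         "expert", "excluded")),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  counts <- table(out$provenance)
  attr(out, "provenance_counts") <- c(as.list(counts),
                                      observed_ge5 = sum(out$provenance == "observed" &
                                                           out$n_obs >= 5))
  out
}

#' Visit-based interaction strength
#'
#' Multiplies each encounter-based link strength by the interaction's mean
#' number of flower visits per encounter. Interactions whose visit estimate
#' is `"excluded"` are removed from the visit-based network and from the
#' companion filtered copy of the encounter network, so the two measures are
#' always compared on an identical link set.
#'
#' @param encounter_network a `bipartite_network` with `measure = "encounter"`
#' @param visit_estimates output of [estimate_visits()]
#' @return list with elements `visit` (the visit-based network) and
#'   `encounter` (the encounter network restricted to the same link set).
#' @export
visit_strength <- function(encounter_network, visit_estimates) {
  stopifnot(inherits(encounter_network, "bipartite_network"),
            encounter_network$measure == "encounter")
  cells <- network_cells(encounter_network)
  pkey <- function(p, z) paste(p, z, sep = "\r")
  idx <- match(pkey(cells$plant, cells$pollinator),
               pkey(visit_estimates$plant, visit_estimates$pollinator))
  if (any(is.na(idx))) {
    bad <- which(is.na(idx))[1L]
    stop(sprintf("no visit estimate for interaction (%s, %s)",
                 cells$plant[bad], cells$pollinator[bad]), call. = FALSE)
  }
  est <- visit_estimates[idx, ]
  keep <- est$provenance != "excluded"
  if (!any(keep)) stop("all interactions excluded: no visit-based network",
                       call. = FALSE)
  vis_cells <- data.frame(plant = cells$plant[keep],
                          pollinator = cells$pollinator[keep],
                          strength = cells$strength[keep] * est$mean_visits[keep],
                          stringsAsFactors = FALSE)
  visit_net <- bipartite_network(vis_cells, measure = "visit")
  enc_filtered <- if (all(keep)) encounter_network else
    filter_links(encounter_network, cells[keep, c("plant", "pollinator")])
  list(visit = visit_net, encounter = enc_filtered)
}

#' Build paired encounter- and visit-based networks from survey records
#'
#' Convenience wrapper running the full pipeline: weekly encounter
#' frequencies, abundance-weighted encounter strengths, visits-per-encounter
#' estimation with the donor/expert imputation hierarchy, and visit-based
#' strengths, with exclusions applied to both networks.
#'
#' @inheritParams weekly_encounter_frequency
#' @inheritParams estimate_visits
#' @return list with `encounter` and `visit` networks (identical link sets),
#'   `estimates` (the per-interaction visit estimates) and
#'   `imputation_report` (counts per provenance class).
#' @export
build_networks <- function(encounters, flower_surveys, visit_samples,
                           donors = NULL, expert_defaults = NULL) {
  wf <- weekly_encounter_frequency(encounters, flower_surveys)
  enc <- encounter_strength(wf, flower_surveys)
  est <- estimate_visits(visit_samples, network_cells(enc),
                         donors = donors, expert_defaults = expert_defaults)
  both <- visit_strength(enc, est)
  list(encounter = both$encounter, visit = both$visit, estimates = est,
       imputation_report = attr(est, "provenance_counts"))
}
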