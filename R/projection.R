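#' Projection profile of a neuron
#'
#' Assigns each terminal branch of the topological minor to the atlas area
#' (and layer) containing its terminal point and accrues the branch's full
#' path length there. Branches terminating outside the configured areas are
#' tallied under \code{"other"}.
#'
#' @param t A \code{topological_minor}.
#' @param a An \code{\link{atlas_volume}}.
#' @param areas Non-empty character vector of area acronyms to profile.
#' @return An object of class \code{projection_profile} with per-area lengths
#'   (\code{area_length_um}), per-area/layer lengths (\code{area_layer}),
#'   terminal counts (\code{area_terminal_count}), a per-terminal table
#'   (\code{terminals}) and the dominant target.
#' @export
projection_profile <- function(t, a, areas) {
  stopifnot(inherits(t, "topological_minor"), inherits(a, "atlas_volume"))
  if (!length(areas)) stop("areas must be nonempty", call. = FALSE)
  areas <- as.character(areas)
  nb <- length(t$terminal_branches)
  if (nb == 0L) {
    terminals <- data.frame(area = character(0), layer = character(0),
                            length_um = numeric(0), x = numeric(0),
                            y = numeric(0), z = numeric(0))
  } else {
    tp <- t$terminal_points
    lab <- label_at(a, tp)
    area <- ifelse(lab$area %in% areas, lab$area, "other")
    terminals <- data.frame(area = area, layer = lab$layer,
                            length_um = t$branch_lengths,
                            x = tp[, 1L], y = tp[, 2L], z = tp[, 3L],
                            stringsAsFactors = FALSE)
  }
  bins <- c(areas, "other")
  area_length <- vapply(bins, function(ar)
    sum(terminals$length_um[terminals$area == ar]), numeric(1))
  area_count <- vapply(bins, function(ar)
    sum(terminals$area == ar), integer(1))
  in_area <- terminals$area != "other" & !is.na(terminals$layer)
  area_layer <- if (any(in_area)) {
    agg <- stats::aggregate(length_um ~ area + layer,
                            data = terminals[in_area, , drop = FALSE], FUN = sum)
    agg[order(agg$area, agg$layer), , drop = FALSE]
  } else {
    data.frame(area = character(0), layer = character(0), length_um = numeric(0))
  }
  p <- structure(list(neuron_id = t$neuron_id,
                      areas = areas,
                      area_length_um = area_length,
                      area_layer = area_layer,
                      area_terminal_count = area_count,
                      terminals = terminals,
                      dominant_target = NA_character_),
                 class = "projection_profile")
  p$dominant_target <- dominant_target(p)
  p
}

#' @export
print.projection_profile <- function(x, ...) {
  cat(sprintf("<projection_profile> %s: dominant %s, %.0f um terminal length in %d branches\n",
              x$neuron_id,
              if (is.na(x$dominant_target)) "none" else x$dominant_target,
              sum(x$area_length_um), sum(x$area_terminal_count)))
  invisible(x)
}

# deterministic area ordering: canonical somatosensory areas first, then
# alphabetical
.area_rank <- function(areas) {
  r <- match(areas, .canonical_areas)
  r[is.na(r)] <- length(.canonical_areas) + rank(areas[is.na(r)])
  r
}

#' Dominant projection target of a profile
#'
#' The configured area receiving the greatest total terminal-branch length.
#' Ties are broken by canonical area order and flagged via the \code{"tie"}
#' attribute; an all-zero profile returns \code{NA}.
#'
#' @param p A \code{projection_profile}.
#' @return An area acronym (or \code{NA}), with attribute \code{tie}.
#' @export
dominant_target <- function(p) {
  len <- p$area_length_um[p$areas]
  if (all(len == 0)) return(structure(NA_character_, tie = FALSE))
  mx <- max(len)
  cand <- p$areas[len == mx]
  structure(cand[order(.area_rank(cand))][1L], tie = length(cand) > 1L)
}

#' Extract the projection motif of a profile
#'
#' Areas receiving at least \code{min_terminal_branches} terminal branches,
#' ordered by descending terminal count (count ties broken by canonical area
#' order). The empty motif is allowed.
#'
#' @param p A \code{projection_profile}.
#' @param min_terminal_branches Minimum terminal branches per area
#'   (default 5).
#' @return Character vector of area acronyms (possibly empty).
#' @export
extract_motif <- function(p, min_terminal_branches = 5) {
  stopifnot(min_terminal_branches >= 1)
  cnt <- p$area_terminal_count[p$areas]
  keep <- cnt >= min_terminal_branches
  ar <- p$areas[keep]
  ar[order(-cnt[keep], .area_rank(ar))]
}

#' Order class of a motif
#'
#' Maps motif size 0/1/2/3/4/>=5 to subthreshold, monofocal, bifurcating,
#' trifurcating, quadrifurcating, higher.
#'
#' @param motif Character vector of motif areas.
#' @return A single character order class.
#' @export
classify_order <- function(motif) {
  k <- length(motif)
  if (k == 0L) "subthreshold"
  else if (k >= 5L) "higher"
  else c("monofocal", "bifurcating", "trifurcating", "quadrifurcating")[k]
}

#' Center/border focality of a multifocal neuron
#'
#' A multifocal neuron is \code{"center"} when at least \code{min_terminals}
#' of its terminal points inside the secondary motif area lie more than
#' \code{min_border_um} from the nearest voxel of the dominant area, and
#' \code{"border"} otherwise. Motifs with fewer than two areas are
#' \code{"not_applicable"}. Only the second-ranked motif area is evaluated.
#'
#' @param t A \code{topological_minor}.
#' @param a An \code{\link{atlas_volume}}.
#' @param motif Motif area list (dominant first).
#' @param min_terminals Terminal count required deep in the secondary area.
#' @param min_border_um Distance threshold in micrometers.
#' @return \code{"center"}, \code{"border"} or \code{"not_applicable"}.
#' @export
classify_focality <- function(t, a, motif, min_terminals = 4,
                              min_border_um = 200) {
  if (length(motif) < 2L) return("not_applicable")
  primary <- motif[1L]; secondary <- motif[2L]
  lab <- label_at(a, t$terminal_points)
  sec_pts <- t$terminal_points[lab$area %in% secondary, , drop = FALSE]
  if (!nrow(sec_pts)) return("border")
  deep <- border_distance(a, sec_pts, primary) > min_border_um
  if (sum(deep) >= min_terminals) "center" else "border"
}

.motif_key <- function(motif) paste(motif, collapse = " - ")
.motif_unkey <- function(key) if (!nzchar(key)) character(0) else
  strsplit(key, " - ", fixed = TRUE)[[1L]]

#' Census of projection motifs over a population
#'
#' Counts neurons per unique (order-sensitive) motif, per order class and per
#' dominant target, with fractions of the total.
#'
#' @param profiles List of \code{projection_profile} objects.
#' @param min_terminal_branches Motif threshold passed to
#'   \code{\link{extract_motif}}.
#' @return A list of class \code{motif_census}: \code{table} (one row per
#'   motif, sorted by descending neuron count), \code{order_counts},
#'   \code{by_dominant}, \code{n} and the per-neuron assignments
#'   (\code{neurons}).
#' @export
motif_census <- function(profiles, min_terminal_branches = 5) {
  n <- length(profiles)
  if (n == 0L) {
    return(structure(list(
      table = data.frame(motif = character(0), n = integer(0),
                         fraction = numeric(0), order_class = character(0)),
      order_counts = data.frame(order_class = character(0), n = integer(0),
                                fraction = numeric(0)),
      by_dominant = table(character(0)),
      n = 0L,
      neurons = data.frame(neuron_id = character(0), motif = character(0),
                           order_class = character(0),
                           dominant = character(0))),
      class = "motif_census"))
  }
  motifs <- lapply(profiles, extract_motif,
                   min_terminal_branches = min_terminal_branches)
  keys <- vapply(motifs, .motif_key, character(1))
  ocl <- vapply(motifs, classify_order, character(1))
  dom <- vapply(profiles, function(p) as.character(p$dominant_target),
                character(1))
  neurons <- data.frame(
    neuron_id = vapply(profiles, `[[`, character(1), "neuron_id"),
    motif = keys, order_class = ocl, dominant = dom,
    stringsAsFactors = FALSE)
  tab <- as.data.frame(table(motif = keys), stringsAsFactors = FALSE)
  names(tab)[2L] <- "n"
  tab$fraction <- tab$n / n
  tab$order_class <- vapply(tab$motif,
                            function(k) classify_order(.motif_unkey(k)),
                            character(1))
  tab <- tab[order(-tab$n, tab$motif), , drop = FALSE]
  rownames(tab) <- NULL
  oc <- as.data.frame(table(order_class = ocl), stringsAsFactors = FALSE)
  names(oc)[2L] <- "n"
  oc$fraction <- oc$n / n
  structure(list(table = tab, order_counts = oc,
                 by_dominant = table(dom, useNA = "ifany"), n = n,
                 neurons = neurons),
            class = "motif_census")
}

#' @export
print.motif_census <- function(x, ...) {
  cat(sprintf("<motif_census> %d neurons, %d unique motifs\n", x$n,
              nrow(x$table)))
  print(head(x$table, 10L))
  invisible(x)
}

#' Binomial significance of multi-area motifs
#'
#' For each multi-area motif, the null joint probability is the product of
#' the marginal per-area targeting probabilities (fraction of neurons whose
#' motif includes the area); the observed number of neurons jointly
#' targeting all motif areas is tested with a two-sided exact binomial test
#' against that null, with Bonferroni correction over the motifs tested.
#'
#' @param census A \code{motif_census}.
#' @param n_neurons Population size (defaults to \code{census$n}).
#' @param alpha Family-wise significance level.
#' @return data.frame with one row per multi-area motif: observed joint
#'   count, null probability, raw and Bonferroni-corrected p-values, and the
#'   significance flag.
#' @export
motif_significance <- function(census, n_neurons = census$n, alpha = 0.05) {
  stopifnot(n_neurons >= 1)
  sets <- lapply(census$table$motif, .motif_unkey)
  multi <- lengths(sets) >= 2L
  if (!any(multi)) {
    return(data.frame(motif = character(0), observed = integer(0),
                      null_p = numeric(0), p_value = numeric(0),
                      p_adj = numeric(0), significant = logical(0)))
  }
  all_areas <- unique(unlist(sets))
  marg <- vapply(all_areas, function(ar)
    sum(census$table$n[vapply(sets, function(s) ar %in% s, logical(1))]) /
      n_neurons, numeric(1))
  names(marg) <- all_areas
  rows <- lapply(which(multi), function(i) {
    s <- sets[[i]]
    observed <- sum(census$table$n[vapply(sets, function(o) all(s %in% o),
                                          logical(1))])
    null_p <- prod(marg[s])
    pv <- binom.test(observed, n_neurons, p = null_p,
                     alternative = "two.sided")$p.value
    data.frame(motif = census$table$motif[i], observed = observed,
               null_p = null_p, p_value = pv, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- pmin(1, out$p_value * nrow(out))
  out$significant <- out$p_adj < alpha
  rownames(out) <- NULL
  out
}

#' Layer distribution of terminal length
#'
#' Per area, the summed terminal-branch length per cortical layer; per
#' neuron, the layer receiving the highest fraction of terminal length in
#' its first and second most-targeted areas.
#'
#' @param profiles List of \code{projection_profile} objects with
#'   layer-resolved lengths.
#' @param area_set Areas to tabulate.
#' @return List with \code{totals} (area x layer matrix of micrometers) and
#'   \code{preferred} (data.frame neuron_id, rank, area, layer).
#' @export
layer_distribution <- function(profiles, area_set) {
  all_layers <- sort(unique(unlist(lapply(profiles,
                                          function(p) p$area_layer$layer))))
  totals <- matrix(0, nrow = length(area_set), ncol = length(all_layers),
                   dimnames = list(area_set, all_layers))
  pref <- list()
  for (p in profiles) {
    al <- p$area_layer
    for (i in seq_len(nrow(al))) {
      if (al$area[i] %in% area_set)
        totals[al$area[i], al$layer[i]] <-
          totals[al$area[i], al$layer[i]] + al$length_um[i]
    }
    len <- p$area_length_um[p$areas]
    ord <- order(-len, .area_rank(p$areas))
    top <- p$areas[ord][len[ord] > 0]
    for (r in seq_len(min(2L, length(top)))) {
      sub <- al[al$area == top[r], , drop = FALSE]
      if (!nrow(sub)) next
      pref[[length(pref) + 1L]] <- data.frame(
        neuron_id = p$neuron_id, rank = r, area = top[r],
        layer = sub$layer[which.max(sub$length_um)],
        stringsAsFactors = FALSE)
    }
  }
  preferred <- if (length(pref)) do.call(rbind, pref) else
    data.frame(neuron_id = character(0), rank = integer(0),
               area = character(0), layer = character(0))
  list(totals = totals, preferred = preferred)
}

#' Barrel-level census
#'
#' Runs the motif machinery at barrel resolution: for each barrel, the
#' neurons sending at least \code{min_terminals} terminal branches to it are
#' partitioned into monofocal/multifocal (from the area-level motif) crossed
#' with single-/multi-barrel (from the barrel-level targeting). The partition
#' sums to the per-barrel total.
#'
#' @param area_profiles Area-level \code{projection_profile} list.
#' @param barrel_profiles Barrel-level \code{projection_profile} list for the
#'   same neurons (atlas with barrel labels), in the same order.
#' @param min_terminals Barrel targeting threshold (default 4).
#' @param min_terminal_branches Area-level motif threshold (default 5).
#' @return data.frame with one row per barrel and columns for the four
#'   groups plus the total.
#' @export
barrel_census <- function(area_profiles, barrel_profiles, min_terminals = 4,
                          min_terminal_branches = 5) {
  stopifnot(length(area_profiles) == length(barrel_profiles))
  barrels <- barrel_profiles[[1L]]$areas
  mono <- vapply(area_profiles, function(p)
    length(extract_motif(p, min_terminal_branches)) == 1L, logical(1))
  targ <- lapply(barrel_profiles, extract_motif,
                 min_terminal_branches = min_terminals)
  single <- lengths(targ) == 1L
  out <- lapply(barrels, function(b) {
    hit <- vapply(targ, function(s) b %in% s, logical(1))
    data.frame(barrel = b,
               monofocal_single = sum(hit & mono & single),
               monofocal_multi = sum(hit & mono & !single),
               multifocal_single = sum(hit & !mono & single),
               multifocal_multi = sum(hit & !mono & !single),
               total = sum(hit),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Export profiles as a TSV table
#'
#' @param profiles List of \code{projection_profile} objects.
#' @param path Optional TSV output path.
#' @param min_terminal_branches Motif threshold.
#' @return data.frame with one row per neuron.
#' @export
profile_table <- function(profiles, path = NULL, min_terminal_branches = 5) {
  rows <- lapply(profiles, function(p) {
    motif <- extract_motif(p, min_terminal_branches)
    cbind(data.frame(neuron_id = p$neuron_id,
                     dominant = as.character(p$dominant_target),
                     motif = .motif_key(motif),
                     order_class = classify_order(motif),
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(p$area_length_um), check.names = FALSE))
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  if (!is.null(path))
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  tab
}
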