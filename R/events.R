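# Censoring-aware event detection: vestibule entries (gate-plane predicate),
# site occupancy (distance hysteresis + minimum dwell), first-binding times,
# binding order, chloride release.

#' Define the vestibule gate
#'
#' The extracellular gate is a salt bridge, not a surface; it is implemented
#' as the plane through the midpoint of the two anchor atoms with normal
#' along the vestibule axis.  An ion is inside the vestibule iff its
#' projection on the axis lies on the intracellular side of that plane and
#' its lateral distance from the axis is at most `lateral_radius` (which
#' excludes bulk ions passing beside the protein).
#'
#' @param anchor_a,anchor_b `AtomSelection`s resolving to exactly one atom
#'   each (e.g. the R104 guanidinium and E493 carboxylate carbons)
#' @param vestibule_axis unit 3-vector pointing into the vestibule
#' @param lateral_radius nm
#' @param min_dwell ns; inside-intervals shorter than this are discarded
#'   (default 0: a pure crossing counts)
#' @return list of class `GateDefinition`
#' @export
gate_definition <- function(anchor_a, anchor_b,
                            vestibule_axis = c(0, 0, -1),
                            lateral_radius = 1.2, min_dwell = 0) {
  stopifnot(inherits(anchor_a, "AtomSelection"),
            inherits(anchor_b, "AtomSelection"))
  if (length(anchor_a$indices) != 1L || length(anchor_b$indices) != 1L)
    stopf("gate_definition: each anchor must resolve to exactly one atom")
  stopifnot(lateral_radius > 0, min_dwell >= 0)
  structure(list(anchor_a = anchor_a, anchor_b = anchor_b,
                 vestibule_axis = vestibule_axis / sqrt(sum(vestibule_axis^2)),
                 lateral_radius = lateral_radius, min_dwell = min_dwell),
            class = "GateDefinition")
}

#' Define a binding site for occupancy detection
#'
#' Occupancy uses distance hysteresis to suppress frame-level flicker: it
#' begins when the ion's distance to the coordinating-atom centroid drops
#' below `entry_cutoff` and is sustained for at least `min_dwell`, and ends
#' at the first frame beyond `exit_cutoff`.  An occupancy still running at
#' the final frame is censored (and kept regardless of its dwell, since its
#' true length is unknown).
#'
#' @param name site name (e.g. `"NA1"`)
#' @param coordinating `AtomSelection` of the coordinating atoms
#' @param entry_cutoff,exit_cutoff nm, with `exit_cutoff > entry_cutoff`
#' @param min_dwell ns
#' @return list of class `SiteDefinition`
#' @export
site_definition <- function(name, coordinating, entry_cutoff = 0.30,
                            exit_cutoff = 0.50, min_dwell = 1.0) {
  stopifnot(inherits(coordinating, "AtomSelection"))
  if (!length(coordinating$indices))
    stopf("site_definition selection error: empty coordinating selection")
  if (!(exit_cutoff > entry_cutoff))
    stopf("site_definition: exit_cutoff must exceed entry_cutoff (hysteresis)")
  stopifnot(min_dwell >= 0)
  structure(list(name = name, coordinating = coordinating,
                 entry_cutoff = entry_cutoff, exit_cutoff = exit_cutoff,
                 min_dwell = min_dwell),
            class = "SiteDefinition")
}

#' Select all ions of an element
#'
#' @param top a `Topology`
#' @param element element symbol, default `"Na"`
#' @return an `AtomSelection`
#' @export
select_ions <- function(top, element = "Na") {
  stopifnot(inherits(top, "Topology"))
  idx <- which(top$atoms$element == element)
  if (!length(idx))
    stopf("selection error: no %s ions in topology", element)
  structure(list(expression = sprintf("element %s", element), indices = idx,
                 atom_ids = top$atoms$atom_id[idx]),
            class = "AtomSelection")
}

## Turn a logical occupancy matrix (frames x ions) into event records.
## `interior_min_frames`: minimum run length (frames) for interior runs;
## runs touching the final frame are kept and censored.
runs_to_events <- function(occ, times, ion_ids, interior_min_frames) {
  nf <- nrow(occ)
  out <- list()
  for (j in seq_len(ncol(occ))) {
    r <- rle(occ[, j])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      censored <- ends[k] == nf
      if (!censored && r$lengths[k] < interior_min_frames) next
      out[[length(out) + 1L]] <- data.frame(
        replica_id = NA_integer_, ion_id = ion_ids[j],
        site = NA_character_, entry_ns = times[starts[k]],
        exit_ns = if (censored) NA_real_ else times[ends[k] + 1L],
        censored = censored)
    }
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(replica_id = integer(), ion_id = integer(),
                  site = character(), entry_ns = numeric(),
                  exit_ns = numeric(), censored = logical())
}

#' Detect vestibule-entry events
#'
#' One event per maximal inside-interval of each selected ion (see
#' [gate_definition()] for the membership predicate); intervals shorter than
#' the gate's `min_dwell` are discarded unless they run to the final frame
#' (censored).
#'
#' @param traj a `Trajectory`
#' @param gate a `GateDefinition`
#' @param ion_selection `AtomSelection` of the ions to track
#' @return data.frame with columns `replica_id`, `ion_id`, `site`
#'   (`"VESTIBULE"`), `entry_ns`, `exit_ns` (NA when censored), `censored`
#' @export
detect_vestibule_entries <- function(traj, gate, ion_selection) {
  stopifnot(inherits(traj, "Trajectory"), inherits(gate, "GateDefinition"),
            inherits(ion_selection, "AtomSelection"))
  nf <- traj$n_frames
  ax <- gate$vestibule_axis
  ia <- gate$anchor_a$indices; ib <- gate$anchor_b$indices
  ions <- ion_selection$indices
  mid <- (traj$coords[, ia, ] + traj$coords[, ib, ]) / 2   # nf x 3
  proj <- matrix(0, nf, length(ions))
  lat2 <- matrix(0, nf, length(ions))
  for (axn in 1:3) {
    rel <- traj$coords[, ions, axn, drop = FALSE]
    dim(rel) <- c(nf, length(ions))
    rel <- rel - mid[, axn]
    proj <- proj + rel * ax[axn]
    lat2 <- lat2 + rel^2
  }
  lat2 <- lat2 - proj^2
  occ <- proj > 0 & lat2 <= gate$lateral_radius^2
  min_frames <- max(1L, as.integer(ceiling(gate$min_dwell / traj$dt)))
  ev <- runs_to_events(occ, traj$times, seq_along(ions), min_frames)
  if (nrow(ev)) { ev$replica_id <- traj$replica_id; ev$site <- "VESTIBULE" }
  ev
}

#' Detect site-occupancy events
#'
#' Hysteresis state machine per ion: occupancy starts when the distance to
#' the unweighted coordinating-atom centroid drops below the entry cutoff,
#' persists while it stays at or below the exit cutoff, and ends at the
#' first frame beyond it.  Interior occupancies shorter than `min_dwell`
#' are discarded; occupancies running to the final frame are censored.
#'
#' @param traj a `Trajectory`
#' @param site a `SiteDefinition`
#' @param ion_selection `AtomSelection` of the ions to track
#' @return event data.frame as in [detect_vestibule_entries()]
#' @export
detect_site_occupancy <- function(traj, site, ion_selection) {
  stopifnot(inherits(traj, "Trajectory"), inherits(site, "SiteDefinition"),
            inherits(ion_selection, "AtomSelection"))
  d <- ion_site_distances(traj, site, ion_selection)
  nf <- nrow(d)
  occ <- matrix(FALSE, nf, ncol(d))
  below_entry <- d < site$entry_cutoff
  within_exit <- d <= site$exit_cutoff
  ## hysteresis, vectorised: within each maximal run of frames at or below
  ## the exit cutoff, occupancy holds from the first frame below the entry
  ## cutoff onward (cb = cumulative entries; c0 = its value at the last
  ## frame outside the exit cutoff, carried forward)
  for (j in seq_len(ncol(d))) {
    be <- below_entry[, j]; we <- within_exit[, j]
    cb <- cumsum(be)
    c0 <- cummax(ifelse(!we, cb, 0L))
    occ[, j] <- we & cb > c0
  }
  min_frames <- max(1L, as.integer(ceiling(site$min_dwell / traj$dt)))
  ev <- runs_to_events(occ, traj$times, seq_len(ncol(d)), min_frames)
  if (nrow(ev)) { ev$replica_id <- traj$replica_id; ev$site <- site$name }
  ev
}

## frames x ions matrix of distances to the coordinating-atom centroid
ion_site_distances <- function(traj, site, ion_selection) {
  ci <- site$coordinating$indices
  ions <- ion_selection$indices
  nf <- traj$n_frames
  d2 <- matrix(0, nf, length(ions))
  for (axn in 1:3) {
    cc <- traj$coords[, ci, axn, drop = FALSE]
    dim(cc) <- c(nf, length(ci))
    com <- rowMeans(cc)
    ip <- traj$coords[, ions, axn, drop = FALSE]
    dim(ip) <- c(nf, length(ions))
    d2 <- d2 + (ip - com)^2
  }
  sqrt(d2)
}

#' Assemble an EventTable
#'
#' @param events event data.frame(s) from the detectors (rbind-able)
#' @param n_replicas total number of replicas in the set (also counting
#'   replicas with no events)
#' @param duration trajectory duration, ns
#' @return the events sorted by (replica_id, entry_ns), classed `EventTable`,
#'   with `n_replicas` and `duration` attributes
#' @export
event_table <- function(events, n_replicas, duration, sites = NULL) {
  stopifnot(is.data.frame(events), is_count(n_replicas), duration > 0)
  if (nrow(events)) {
    if (any(events$entry_ns < 0 | events$entry_ns > duration))
      stopf("event_table integrity error: entry time outside [0, duration]")
    bad <- !events$censored & events$exit_ns <= events$entry_ns
    if (any(bad, na.rm = TRUE))
      stopf("event_table integrity error: exit time not after entry time")
    events <- events[order(events$replica_id, events$entry_ns), ,
                     drop = FALSE]
    rownames(events) <- NULL
  }
  structure(events, class = c("EventTable", "data.frame"),
            n_replicas = as.integer(n_replicas), duration = duration,
            sites = unique(c(sites, as.character(events$site))))
}

#' Per-replica first binding times for one site
#'
#' @param table an `EventTable`
#' @param site_name site to extract
#' @return data.frame with one row per replica: `replica_id`, `time` (ns of
#'   the earliest entry, NA when censored) and `censored`; carries the
#'   table's `duration` and the event-frame `dt` (if present) as attributes
#' @export
first_binding_times <- function(table, site_name) {
  stopifnot(inherits(table, "EventTable"), is.character(site_name),
            length(site_name) == 1L)
  known <- attr(table, "sites")
  if (length(known) && !site_name %in% known)
    stopf("first_binding_times key error: unknown site '%s' (table covers: %s)",
          site_name, paste(known, collapse = ", "))
  n <- attr(table, "n_replicas")
  sub <- table[table$site == site_name, , drop = FALSE]
  t <- rep(NA_real_, n)
  if (nrow(sub)) {
    agg <- tapply(sub$entry_ns, sub$replica_id, min)
    ids <- as.integer(names(agg))
    keep <- ids >= 1L & ids <= n
    t[ids[keep]] <- as.numeric(agg)[keep]
  }
  out <- data.frame(replica_id = seq_len(n), time = t, censored = is.na(t))
  attr(out, "duration") <- attr(table, "duration")
  out
}

#' Binding-order counts for the two deep sites
#'
#' Partitions all replicas into six exclusive categories by comparing the
#' first-binding times of NA1 and NA2.  Equal first times go to the `tie`
#' category (never broken randomly, so reported statistics are
#' deterministic).  Counts always sum to the number of replicas.
#'
#' @param table an `EventTable` containing NA1/NA2 events
#' @return named integer vector with elements `NA2_first`, `NA1_first`,
#'   `tie`, `only_NA1`, `only_NA2`, `neither`
#' @export
binding_order_counts <- function(table) {
  attr(table, "sites") <- unique(c(attr(table, "sites"), "NA1", "NA2"))
  t1 <- first_binding_times(table, "NA1")$time
  t2 <- first_binding_times(table, "NA2")$time
  both <- !is.na(t1) & !is.na(t2)
  c(NA2_first = sum(both & t2 < t1),
    NA1_first = sum(both & t1 < t2),
    tie = sum(both & t1 == t2),
    only_NA1 = sum(!is.na(t1) & is.na(t2)),
    only_NA2 = sum(is.na(t1) & !is.na(t2)),
    neither = sum(is.na(t1) & is.na(t2)))
}

#' Detect release of an initially bound ion and its exit route
#'
#' For an ion that starts within the site's entry cutoff: the release time
#' is the first frame beyond the exit cutoff, and `passed_via` records
#' whether the ion comes within the via-site's entry cutoff during the 1 ns
#' window from release (the chloride-through-NA1 observation).
#'
#' @param traj a `Trajectory`
#' @param site `SiteDefinition` the ion starts in
#' @param via_site `SiteDefinition` defining the exit route of interest
#' @param ion_selection `AtomSelection` of candidate ions (typically the one
#'   chloride)
#' @return data.frame with `ion_id`, `release_ns`, `passed_via`; zero rows
#'   if the ion is never released
#' @export
detect_release <- function(traj, site, via_site, ion_selection) {
  d <- ion_site_distances(traj, site, ion_selection)
  dvia <- ion_site_distances(traj, via_site, ion_selection)
  out <- list()
  for (j in seq_len(ncol(d))) {
    if (d[1L, j] > site$entry_cutoff)
      stopf("detect_release precondition error: ion %d not initially bound (distance %.3f nm > %.3f nm)",
            j, d[1L, j], site$entry_cutoff)
    rel <- which(d[, j] > site$exit_cutoff)[1L]
    if (is.na(rel)) next
    wnd <- which(traj$times >= traj$times[rel] &
                 traj$times <= traj$times[rel] + 1)
    out[[length(out) + 1L]] <- data.frame(
      ion_id = j, release_ns = traj$times[rel],
      passed_via = any(dvia[wnd, j] < via_site$entry_cutoff))
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(ion_id = integer(), release_ns = numeric(),
                  passed_via = logical())
}

#' Serialise an EventTable
#'
#' @param table an `EventTable`
#' @param path output path; format from the extension (`.csv` or `.json`)
#' @return `path`, invisibly
#' @export
write_event_table <- function(table, path) {
  stopifnot(inherits(table, "EventTable"))
  df <- as.data.frame(table)[, c("replica_id", "ion_id", "site", "entry_ns",
                                 "exit_ns", "censored")]
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(list(n_replicas = attr(table, "n_replicas"),
                              duration = attr(table, "duration"),
                              events = df),
                         path, auto_unbox = TRUE, digits = NA, na = "null",
                         dataframe = "columns")
  } else {
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
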