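# Four-pass GPS cleaning: blocklist removal, iterative speed filtering,
# spike-geometry removal, removal of fixes stranded between removed
# neighbours, and stationary-run collapse. Fixes are only ever removed,
# never moved; every removal carries a reason label.

#' Step metrics of a trajectory
#'
#' Speeds are assigned to the LATER fix of each pair: the speed the animal
#' must have sustained to arrive there. Turn angle at an interior fix is the
#' angle in degrees between the incoming and outgoing displacement
#' directions, 0 = straight on, 180 = full reversal.
#'
#' @param traj data.frame `(t, x, y)` for one animal, strictly increasing
#'   `t`.
#' @return data.frame with per-fix `dist` (m), `dt` (min), `speed` (m/min)
#'   (NA at the first fix) and `turn_angle` (NA at both ends).
#' @export
compute_step_metrics <- function(traj) {
  n <- nrow(traj)
  stopifnot(n >= 2)
  dtv <- as.numeric(difftime(traj$t[-1], traj$t[-n], units = "mins"))
  if (any(dtv <= 0)) {
    i <- which(dtv <= 0)[1]
    stop(sprintf("non-positive time step between fixes %d and %d", i, i + 1))
  }
  dx <- diff(traj$x); dy <- diff(traj$y)
  dist <- sqrt(dx^2 + dy^2)
  speed <- dist / dtv
  turn <- rep(NA_real_, n)
  if (n >= 3) {
    v1x <- dx[-(n - 1)]; v1y <- dy[-(n - 1)]
    v2x <- dx[-1]; v2y <- dy[-1]
    dot <- v1x * v2x + v1y * v2y
    nrm <- sqrt(v1x^2 + v1y^2) * sqrt(v2x^2 + v2y^2)
    cosang <- ifelse(nrm > 0, pmin(1, pmax(-1, dot / nrm)), NA_real_)
    turn[2:(n - 1)] <- acos(cosang) * 180 / pi
  }
  data.frame(dist = c(NA, dist), dt = c(NA, dtv), speed = c(NA, speed),
             turn_angle = turn)
}

# arriving speeds for a subset of rows (indices into traj, kept order)
.arriving_speeds <- function(traj, keep) {
  m <- length(keep)
  if (m < 2) return(numeric(0))
  dtv <- as.numeric(difftime(traj$t[keep[-1]], traj$t[keep[-m]],
                             units = "mins"))
  d <- sqrt(diff(traj$x[keep])^2 + diff(traj$y[keep])^2)
  d / dtv
}

#' Iterative speed filter
#'
#' Removes, one at a time, the fix with the largest arriving speed strictly
#' above `threshold` (earliest fix on ties), recomputing bridging speeds
#' across each gap, until no arriving speed exceeds the threshold. An
#' arriving speed exactly at the threshold is retained.
#'
#' @param traj per-animal fix data.frame `(t, x, y)`.
#' @param threshold m/min.
#' @return list `traj` (survivors), `removed` (original row indices).
#' @export
filter_speed <- function(traj, threshold = 100) {
  n <- nrow(traj)
  keep <- seq_len(n)
  removed <- integer(0)
  repeat {
    sp <- .arriving_speeds(traj, keep)
    over <- which(sp > threshold)
    if (!length(over)) break
    worst <- over[which.max(sp[over])]      # which.max takes earliest tie
    victim <- keep[worst + 1L]              # speeds attach to the later fix
    removed <- c(removed, victim)
    keep <- setdiff(keep, victim)
    if (length(keep) < 2) break
  }
  list(traj = traj[keep, , drop = FALSE], removed = sort(removed),
       kept = keep)
}

.spike_predicate <- function(sp_in, sp_out, turn, spike_speed, angle_range) {
  !is.na(turn) & sp_in >= spike_speed & sp_out >= spike_speed &
    turn >= angle_range[1] & turn <= angle_range[2]
}

#' Spike-location filter
#'
#' An interior fix is a spike when both its arriving and departing legs are
#' at least `spike_speed` and the turning angle lies in `angle_range`
#' (180 = straight-back reversal): an implausible fast out-and-back. A
#' single left-to-right pass removes the apex fix and recomputes the local
#' metrics before continuing.
#'
#' @param traj per-animal fix data.frame `(t, x, y)`.
#' @param spike_speed m/min, inclusive.
#' @param angle_range length-2 degrees, inclusive.
#' @return list `traj`, `removed` (original row indices), `kept`.
#' @export
filter_spikes <- function(traj, spike_speed = 15, angle_range = c(165, 180)) {
  n <- nrow(traj)
  keep <- seq_len(n)
  removed <- integer(0)
  i <- 2L
  while (i < length(keep)) {
    a <- keep[i - 1L]; b <- keep[i]; d <- keep[i + 1L]
    dt1 <- as.numeric(difftime(traj$t[b], traj$t[a], units = "mins"))
    dt2 <- as.numeric(difftime(traj$t[d], traj$t[b], units = "mins"))
    v1x <- traj$x[b] - traj$x[a]; v1y <- traj$y[b] - traj$y[a]
    v2x <- traj$x[d] - traj$x[b]; v2y <- traj$y[d] - traj$y[b]
    l1 <- sqrt(v1x^2 + v1y^2); l2 <- sqrt(v2x^2 + v2y^2)
    turn <- if (l1 > 0 && l2 > 0)
      acos(pmin(1, pmax(-1, (v1x * v2x + v1y * v2y) / (l1 * l2)))) * 180 / pi
    else NA_real_
    if (isTRUE(.spike_predicate(l1 / dt1, l2 / dt2, turn,
                                spike_speed, angle_range))) {
      removed <- c(removed, b)
      keep <- keep[-i]
      # stay at the same position: the old C is now the candidate apex
    } else {
      i <- i + 1L
    }
  }
  list(traj = traj[keep, , drop = FALSE], removed = sort(removed),
       kept = keep)
}

#' Remove fixes stranded between removed neighbours
#'
#' A surviving fix whose immediate predecessor AND successor in the ORIGINAL
#' sequence were both removed by earlier passes is itself removed.
#'
#' @param n_original number of fixes in the original sequence.
#' @param removed_so_far original indices removed by earlier passes.
#' @return original indices to remove in this pass.
#' @export
between_removed_indices <- function(n_original, removed_so_far) {
  gone <- rep(FALSE, n_original)
  gone[removed_so_far] <- TRUE
  cand <- which(!gone)
  cand <- cand[cand > 1 & cand < n_original]
  cand[gone[cand - 1L] & gone[cand + 1L]]
}

#' Collapse stationary runs
#'
#' Maximal runs of consecutive fixes whose successive displacement is at
#' most `tol` metres are reduced to their first fix.
#'
#' @param traj per-animal fix data.frame `(t, x, y)`.
#' @param tol metres; the default treats only bit-identical coordinates as
#'   stationary.
#' @return list `traj`, `removed` (original row indices), `kept`.
#' @export
collapse_stationary <- function(traj, tol = 1e-9) {
  n <- nrow(traj)
  if (n < 2) return(list(traj = traj, removed = integer(0), kept = seq_len(n)))
  d <- sqrt(diff(traj$x)^2 + diff(traj$y)^2)
  drop <- c(FALSE, d <= tol)
  list(traj = traj[!drop, , drop = FALSE], removed = which(drop),
       kept = which(!drop))
}

.in_blocklist <- function(x, y, blocklist) {
  hit <- rep(FALSE, length(x))
  for (b in blocklist)
    hit <- hit | (sqrt((x - b$x)^2 + (y - b$y)^2) <= b$radius)
  hit
}

#' Run the full cleaning pipeline on one or more animals
#'
#' Pass order: coordinate blocklist, iterative speed filter, spike filter,
#' between-removed rule, stationary collapse. Surviving fixes keep their
#' original coordinates and order.
#'
#' @param fixes data.frame `(animal_id, t, x, y)`.
#' @param config a [roam_config()].
#' @return list with `fixes` (cleaned), `report` (class `filter_report`):
#'   per-animal and total removal counts per pass plus per-fix reason labels
#'   (`retained`, `blocklist`, `speed`, `spike`, `between`, `stationary`).
#' @export
run_filter_pipeline <- function(fixes, config = roam_config()) {
  ids <- unique(fixes$animal_id)
  out <- vector("list", length(ids))
  reports <- vector("list", length(ids))
  for (k in seq_along(ids)) {
    traj <- fixes[fixes$animal_id == ids[k], , drop = FALSE]
    rownames(traj) <- NULL
    n <- nrow(traj)
    reason <- rep("retained", n)

    bl <- which(.in_blocklist(traj$x, traj$y, config$blocklist))
    reason[bl] <- "blocklist"
    alive <- setdiff(seq_len(n), bl)

    sub <- traj[alive, , drop = FALSE]
    if (nrow(sub) >= 2) {
      fs <- filter_speed(sub, config$speed_threshold)
      reason[alive[fs$removed]] <- "speed"
      alive <- alive[fs$kept]
    }

    sub <- traj[alive, , drop = FALSE]
    if (nrow(sub) >= 3) {
      fk <- filter_spikes(sub, config$spike_speed, config$spike_angle_range)
      reason[alive[fk$removed]] <- "spike"
      alive <- alive[fk$kept]
    }

    btw <- between_removed_indices(n, which(reason != "retained"))
    btw <- intersect(btw, alive)
    reason[btw] <- "between"
    alive <- setdiff(alive, btw)

    sub <- traj[alive, , drop = FALSE]
    if (nrow(sub) >= 2) {
      st <- collapse_stationary(sub, config$stationary_tol)
      reason[alive[st$removed]] <- "stationary"
      alive <- alive[st$kept]
    }

    if (length(alive) < 2)
      warning("animal ", ids[k], " has < 2 fixes after filtering; ",
              "flagged unusable")
    out[[k]] <- traj[alive, , drop = FALSE]
    reports[[k]] <- data.frame(
      animal_id = ids[k], input = n,
      blocklist = sum(reason == "blocklist"),
      speed = sum(reason == "speed"),
      spike = sum(reason == "spike"),
      between = sum(reason == "between"),
      stationary = sum(reason == "stationary"),
      retained = sum(reason == "retained"),
      usable = length(alive) >= 2,
      stringsAsFactors = FALSE)
    reports[[k]]$reasons <- list(reason)
  }
  report <- do.call(rbind, reports)
  class(report) <- c("filter_report", class(report))
  cleaned <- do.call(rbind, out)
  rownames(cleaned) <- NULL
  list(fixes = cleaned, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  tot <- colSums(x[, c("input", "blocklist", "speed", "spike", "between",
                       "stationary", "retained")])
  cat("<filter_report> ", nrow(x), " animal(s)\n", sep = "")
  cat(sprintf("  input %d | blocklist %d speed %d spike %d between %d stationary %d | retained %d\n",
              tot["input"], tot["blocklist"], tot["speed"], tot["spike"],
              tot["between"], tot["stationary"], tot["retained"]))
  invisible(x)
}
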