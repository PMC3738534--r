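# Hydrogen-bond detection and occupancy/lifetime statistics. A contact is
# bonded in a frame when the donor--acceptor heavy-atom distance is within
# the cutoff and some donor hydrogen keeps the D-H...A arrangement within
# the angular cutoff of linearity. Occupancy is the bonded fraction of
# frames; lifetimes are contiguous bonded runs scaled by the frame spacing.

atom_ref <- function(resno, name) list(resno = as.integer(resno),
                                       name = toupper(name))

resolve_atom <- function(traj, ref, what, multiple_ok = FALSE) {
  i <- which(traj$atoms$resno == ref$resno &
               toupper(traj$atoms$name) == ref$name)
  if (length(i) == 0L)
    stop(what, " atom ", ref$name, "@", ref$resno, " not found")
  if (length(i) > 1L && !multiple_ok)
    stop("ambiguous ", what, " selection ", ref$name, "@", ref$resno,
         ": ", length(i), " atoms match")
  i
}

#' Hydrogen-bond specification
#'
#' Names the donor and acceptor heavy atoms (atom name + residue number) and
#' the geometric cutoffs. The default cutoffs are 3.5 Angstrom on the
#' donor--acceptor distance and 30 degrees on the deviation of the
#' D-H...A angle from linearity (i.e. D-H...A >= 150 degrees), the
#' convention of standard MD hydrogen-bond analysis.
#'
#' @param donor,acceptor Lists `list(resno =, name =)` naming one heavy atom
#'   each (see also [hbond_stats()] examples).
#' @param hydrogen Optional explicit hydrogen atom reference. When `NULL`,
#'   hydrogens covalently close to the donor (within 1.3 Angstrom in the
#'   first frame, name starting with H) are used; if the roster carries no
#'   such hydrogen the angle test is skipped (distance-only fallback,
#'   flagged in the result).
#' @param d_cut Donor--acceptor distance cutoff, Angstrom.
#' @param a_cut Maximum deviation of D-H...A from 180 degrees, degrees.
#' @return Object of class `hbond_spec`.
#' @export
hbond_spec <- function(donor, acceptor, hydrogen = NULL,
                       d_cut = 3.5, a_cut = 30) {
  stopifnot(d_cut > 0, a_cut > 0, a_cut <= 90)
  as_ref <- function(x) {
    if (is.list(x) && all(c("resno", "name") %in% names(x)))
      atom_ref(x$resno, x$name)
    else stop("atom references must be list(resno =, name =)")
  }
  structure(list(donor = as_ref(donor), acceptor = as_ref(acceptor),
                 hydrogen = if (!is.null(hydrogen)) as_ref(hydrogen),
                 d_cut = d_cut, a_cut = a_cut),
            class = "hbond_spec")
}

# Resolve donor/hydrogen/acceptor indices once per trajectory.
hbond_atoms <- function(traj, spec) {
  di <- resolve_atom(traj, spec$donor, "donor")
  ai <- resolve_atom(traj, spec$acceptor, "acceptor")
  if (!is.null(spec$hydrogen)) {
    hi <- resolve_atom(traj, spec$hydrogen, "hydrogen", multiple_ok = TRUE)
  } else {
    cand <- which(traj$atoms$resno == spec$donor$resno &
                    grepl("^H", toupper(traj$atoms$name)))
    if (length(cand)) {
      fc <- frame_coords(traj, 1)
      dd <- sqrt(colSums((t(fc[cand, , drop = FALSE]) - fc[di, ])^2))
      hi <- cand[dd <= 1.3]
    } else hi <- integer(0)
  }
  list(donor = di, hydrogen = hi, acceptor = ai,
       distance_only = length(hi) == 0L)
}

hbond_eval <- function(fc, at, spec) {
  d <- fc[at$donor, ]; a <- fc[at$acceptor, ]
  dist <- sqrt(sum((d - a)^2))
  if (dist > spec$d_cut) return(FALSE)
  if (at$distance_only) return(TRUE)
  for (hi in at$hydrogen) {
    h <- fc[hi, ]
    v1 <- d - h; v2 <- a - h
    ang <- acos(max(-1, min(1, sum(v1 * v2) /
                              sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
    if (180 - ang <= spec$a_cut) return(TRUE)
  }
  FALSE
}

#' Evaluate a hydrogen bond in a single frame
#'
#' @param traj A `g4_trajectory`.
#' @param frame 1-based frame index.
#' @param spec An [hbond_spec()].
#' @return Logical: bonded in this frame.
#' @export
hbond_frame <- function(traj, frame, spec) {
  stopifnot(inherits(traj, "g4_trajectory"), inherits(spec, "hbond_spec"))
  at <- hbond_atoms(traj, spec)
  hbond_eval(frame_coords(traj, frame), at, spec)
}

#' Hydrogen-bond occupancy and lifetime over a trajectory
#'
#' Evaluates the bond in every frame of the (optionally windowed)
#' trajectory. Occupancy is the bonded fraction of frames; events are
#' maximal contiguous bonded runs (a single broken frame ends a run unless
#' `gap` allows bridging); the mean lifetime is the mean run length times
#' the frame spacing.
#'
#' @inheritParams hbond_frame
#' @param start,end 1-based frame window (defaults: whole trajectory).
#' @param gap Number of consecutive broken frames tolerated inside one
#'   event. Default 0: no gap tolerance.
#' @return Object of class `hbond_stats`: `occupancy` (fraction),
#'   `mean_lifetime` (ps), `n_events`, the per-frame logical `bonded`
#'   series, `distance_only` flag and `label` (`"N6@19 -> O4@6"` style).
#' @export
hbond_stats <- function(traj, spec, start = 1L, end = n_frames(traj),
                        gap = 0L) {
  stopifnot(inherits(traj, "g4_trajectory"), inherits(spec, "hbond_spec"))
  nf <- n_frames(traj)
  if (start < 1L || end > nf || start > end)
    stop("frame window [", start, ", ", end, "] outside trajectory (1..",
         nf, ")")
  at <- hbond_atoms(traj, spec)
  frames <- seq.int(start, end)
  bonded <- vapply(frames, function(f) hbond_eval(frame_coords(traj, f),
                                                  at, spec), logical(1))
  runs_mask <- bonded
  if (gap > 0L && any(bonded)) {
    r <- rle(runs_mask)
    inner <- seq_along(r$values)
    bridge <- !r$values & r$lengths <= gap &
      inner > 1L & inner < length(r$values)
    r$values[bridge] <- TRUE
    runs_mask <- inverse.rle(r)
  }
  r <- rle(runs_mask)
  ev <- r$lengths[r$values]
  n_events <- length(ev)
  mean_lifetime <- if (n_events) mean(ev) * traj$frame_spacing else 0
  lab <- sprintf("%s@%d -> %s@%d", spec$donor$name, spec$donor$resno,
                 spec$acceptor$name, spec$acceptor$resno)
  structure(list(occupancy = mean(bonded), mean_lifetime = mean_lifetime,
                 n_events = n_events, bonded = bonded, frames = frames,
                 distance_only = at$distance_only, label = lab,
                 series = data.frame(
                   frame = frames,
                   time_ps = (frames - 1) * traj$frame_spacing,
                   bonded = as.integer(bonded))),
            class = "hbond_stats")
}

#' @export
print.hbond_stats <- function(x, ...) {
  cat(sprintf("hbond %s: occupancy %.1f%%, mean lifetime %.1f ps, %d event(s)%s\n",
              x$label, 100 * x$occupancy, x$mean_lifetime, x$n_events,
              if (x$distance_only) " [distance-only: no hydrogen in roster]"
              else ""))
  invisible(x)
}
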