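#' Summarize protein-ligand contact counts across replicas
#'
#' Takes one replica set of atomic contact-count traces (as from
#' `gmx mindist -on`) per simulation group and returns the per-group
#' mean/SD trace. Counts must be non-negative.
#'
#' @param groups A list of `replica_set` objects (one per group), or one
#'   `replica_set`.
#' @return A list of `summary_trace` tibbles (or a single one if a single
#'   set was given).
#' @export
contacts_summary <- function(groups) {
  single <- inherits(groups, "replica_set")
  if (single) groups <- list(groups)
  out <- lapply(groups, function(rs) {
    if (any(rs$value < 0)) {
      stop("contact counts must be non-negative", call. = FALSE)
    }
    summarize_replicas(align_replicas(rs))
  })
  if (single) out[[1]] else out
}

#' Sum contacts over selected hydrophobic residues
#'
#' The hydrophobic-contact analysis restricts contact counting to
#' user-specified hydrophobic residues: per replica, the per-residue contact
#' traces of the selected residues are summed at every timepoint, and the
#' summed traces are then averaged across replicas.
#'
#' @param per_residue A named list mapping residue identifiers (e.g.
#'   `"LEU34"`) to `replica_set` objects of that residue's contact counts;
#'   all sets must hold the same replicas on the same axis.
#' @param selection Character vector of residue identifiers to include
#'   (non-empty, unique).
#' @return A `summary_trace` of the summed contacts, mean/SD across replicas.
#' @export
hydrophobic_contacts <- function(per_residue, selection) {
  if (length(selection) == 0L) {
    stop("hydrophobic residue selection is empty", call. = FALSE)
  }
  if (anyDuplicated(selection)) {
    stop("hydrophobic residue selection has duplicates: ",
         paste(selection[duplicated(selection)], collapse = ", "),
         call. = FALSE)
  }
  missing <- setdiff(selection, names(per_residue))
  if (length(missing)) {
    stop("selected residue(s) absent from the per-residue data: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  sets <- lapply(per_residue[selection], align_replicas)
  ref <- sets[[1]]
  parts_ref <- rs_split(ref)
  summed <- parts_ref
  for (k in seq_along(sets)[-1]) {
    parts <- rs_split(sets[[k]])
    if (!identical(names(parts), names(parts_ref))) {
      stop("per-residue replica sets disagree in replica ids", call. = FALSE)
    }
    for (id in names(parts)) {
      if (length(parts[[id]]$time) != length(summed[[id]]$time) ||
          any(parts[[id]]$time != summed[[id]]$time)) {
        stop("per-residue replica sets disagree in time axes", call. = FALSE)
      }
      summed[[id]]$value <- summed[[id]]$value + parts[[id]]$value
    }
  }
  rs <- rs_rebuild(summed, ref)
  if (any(rs$value < 0)) {
    stop("contact counts must be non-negative", call. = FALSE)
  }
  summarize_replicas(rs)
}

#' Summarize minimum protein-ligand distances across replicas
#'
#' Per-group mean/SD traces of the shortest ligand-protein distance (nm, as
#' from `gmx mindist -od`). Frames whose mean distance exceeds the
#' dissociation threshold are flagged in the returned attribute
#' `dissociation_frames` (advisory, not a plot element): sustained excursions
#' beyond ~0.6 nm suggest the ligand has left the binding site.
#'
#' @param groups A list of `replica_set` objects of distance traces, or one
#'   set.
#' @param dissociation_nm Threshold in nm (default 0.6).
#' @return `summary_trace`(s) with attribute `dissociation_frames` (integer
#'   indices of flagged frames).
#' @export
min_distance_summary <- function(groups, dissociation_nm = 0.6) {
  single <- inherits(groups, "replica_set")
  if (single) groups <- list(groups)
  out <- lapply(groups, function(rs) {
    if (any(rs$value < 0)) {
      stop("distances must be non-negative", call. = FALSE)
    }
    st <- summarize_replicas(align_replicas(rs))
    flagged <- which(st$mean > dissociation_nm)
    if (length(flagged)) {
      message(sprintf(
        "group '%s': mean min-distance exceeds %.2f nm at %d of %d frames (possible dissociation)",
        attr(st, "group_label"), dissociation_nm, length(flagged), nrow(st)))
    }
    attr(st, "dissociation_frames") <- flagged
    st
  })
  if (single) out[[1]] else out
}
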