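# Walk-mode label refinement and 12-step transition segmentation.

.zscore_cols <- function(m) {
  mu <- colMeans(m)
  sd <- apply(m, 2, stats::sd)
  sd[sd == 0] <- 1
  sweep(sweep(m, 2, mu), 2, sd, "/")
}

.nn1 <- function(query, ref, chunk = 1024L) {
  # index of the nearest reference row for each query row (Euclidean)
  rs_ref <- rowSums(ref^2)
  out <- integer(nrow(query))
  for (s in seq(1, nrow(query), by = chunk)) {
    e <- min(s + chunk - 1L, nrow(query))
    q <- query[s:e, , drop = FALSE]
    d2 <- outer(rowSums(q^2), rs_ref, "+") - 2 * tcrossprod(q, ref)
    out[s:e] <- max.col(-d2, ties.method = "first")
  }
  out
}

#' Refine walk-mode labels near transition boundaries
#'
#' Provisional (possibly imprecise) labels are kept for high-confidence
#' interior frames (at least six steps away from every provisional boundary).
#' Frames within six steps of a boundary are reassigned the label of their
#' nearest reference frame in joint-angle space (1-nearest-neighbour,
#' Euclidean distance on z-scored sagittal hip/knee/ankle angles of both
#' legs). A run-length smoothing then removes per-step label runs shorter than
#' two steps, a deterministic stand-in for manual outlier correction, leaving
#' one boundary per transition region.
#'
#' @param frames frame table with joint-angle columns and provisional
#'   `mode_label`.
#' @param steps step table from [detect_steps()] (provisional labels).
#' @param ref_max maximum number of reference frames used in the 1-NN scan
#'   (deterministic thinning; keeps the search tractable).
#' @return list with `frames` and `steps`, both with refined `mode_label`.
#' @export
refine_walk_mode_labels <- function(frames, steps, ref_max = 2000L) {
  n_steps <- nrow(steps)
  step_lab <- as.character(steps$mode_label)
  bounds <- which(step_lab[-1] != step_lab[-n_steps])  # boundary after step b
  if (length(bounds) == 0) return(list(frames = frames, steps = steps))

  # step distance rule: step s is interior iff s <= b-6 or s >= b+7 for all b
  near <- rep(FALSE, n_steps)
  for (b in bounds) {
    idx <- max(1, b - 5):min(n_steps, b + 6)
    near[idx] <- TRUE
  }

  edges <- c(steps$t_start, steps$t_end[n_steps])
  fr_step <- findInterval(frames$timestamp, edges)
  in_steps <- fr_step >= 1 & fr_step <= n_steps
  fr_step_cl <- pmin(pmax(fr_step, 1L), n_steps)

  feats <- .zscore_cols(as.matrix(frames[, c("hip_l", "hip_r", "knee_l",
                                             "knee_r", "ankle_l",
                                             "ankle_r")]))
  ref_idx <- which(in_steps & !near[fr_step_cl])
  query_idx <- which(in_steps & near[fr_step_cl])
  fr_lab <- as.character(frames$mode_label)
  if (length(ref_idx) == 0) {
    warning("empty reference set; provisional labels kept")
  } else if (length(query_idx) > 0) {
    if (length(ref_idx) > ref_max)
      ref_idx <- ref_idx[round(seq(1, length(ref_idx), length.out = ref_max))]
    # modes with no reference frames keep their provisional labels
    ref_modes <- unique(fr_lab[ref_idx])
    orphan <- setdiff(unique(fr_lab[query_idx]), ref_modes)
    if (length(orphan) > 0) {
      warning("no reference frames for mode(s) ",
              paste(orphan, collapse = ", "),
              "; provisional labels kept there")
      query_idx <- query_idx[!(fr_lab[query_idx] %in% orphan)]
    }
    if (length(query_idx) > 0) {
      nn <- .nn1(feats[query_idx, , drop = FALSE],
                 feats[ref_idx, , drop = FALSE])
      fr_lab[query_idx] <- fr_lab[ref_idx][nn]
    }
  }

  # per-step majority label, then run-length smoothing (runs < 2 steps merge
  # into the preceding run)
  maj <- function(x) names(which.max(table(x)))
  new_lab <- vapply(seq_len(n_steps), function(s) {
    v <- fr_lab[which(fr_step == s)]
    if (length(v) == 0) step_lab[s] else maj(v)
  }, character(1))
  repeat {
    r <- rle(new_lab)
    short <- which(r$lengths < 2)
    if (length(short) == 0 || length(r$lengths) == 1) break
    k <- short[1]
    ends <- cumsum(r$lengths)
    idx <- (ends[k] - r$lengths[k] + 1):ends[k]
    new_lab[idx] <- if (k > 1) r$values[k - 1] else r$values[2]
  }
  steps$mode_label <- new_lab
  frames$mode_label <- new_lab[fr_step_cl]
  list(frames = frames, steps = steps)
}

#' Extract 12-step transition instances
#'
#' For each change in the per-step walk-mode label, collects the six steps
#' before and six after the change. An instance is emitted only when all
#' twelve steps exist, are valid, and carry complete features; relative step
#' indices -6..-1, +1..+6 are assigned (no index 0). Transitions closer than
#' twelve steps to each other are both discarded with a warning.
#'
#' @param steps step table with features and final mode labels.
#' @param feature_vars feature columns that must be complete.
#' @param participant_id,lap_id provenance tags stored per instance.
#' @return long data.frame: one row per (instance, relative step) with
#'   `instance`, `category` ("from – to"), `participant`, `lap`,
#'   `boundary_step`, `rel_index`, and the feature columns.
#' @export
extract_transitions <- function(steps,
                                feature_vars = c("dl_norm", "dp_norm",
                                                 "dtheta", "dalpha", "dgamma"),
                                participant_id = 1L, lap_id = 1L) {
  n <- nrow(steps)
  lab <- as.character(steps$mode_label)
  bounds <- which(lab[-1] != lab[-n])
  if (length(bounds) >= 2) {
    gaps <- diff(bounds)
    clash <- which(gaps < 12)
    if (length(clash) > 0) {
      drop <- unique(c(clash, clash + 1))
      warning(sprintf("%d overlapping transition(s) closer than 12 steps discarded",
                      length(drop)))
      bounds <- bounds[-drop]
    }
  }
  out <- list()
  inst <- 0L
  for (b in bounds) {
    if (b - 5 < 1 || b + 6 > n) next
    idx <- (b - 5):(b + 6)
    win <- steps[idx, ]
    feats_ok <- all(!is.na(as.matrix(win[, feature_vars])))
    if (!all(win$valid) || !feats_ok) next
    inst <- inst + 1L
    rel <- c(-6:-1, 1:6)
    out[[inst]] <- cbind(
      data.frame(instance = inst,
                 category = paste(lab[b], "–", lab[b + 1]),
                 participant = participant_id, lap = lap_id,
                 boundary_step = b, rel_index = rel),
      win[, feature_vars])
  }
  if (length(out) == 0)
    return(data.frame(instance = integer(), category = character(),
                      participant = integer(), lap = integer(),
                      boundary_step = integer(), rel_index = integer()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' IQR outlier removal per transition category
#'
#' Within each category, for each feature variable and each relative step
#' index, values outside `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]` (quartiles by linear
#' interpolation, type 7) are flagged; an instance is removed when any of its
#' cells is flagged. Categories with fewer than four instances pass through
#' unchanged with a warning.
#'
#' @param transitions long instance table from [extract_transitions()].
#' @param feature_vars feature columns screened for outliers.
#' @return the filtered long table.
#' @export
iqr_filter <- function(transitions,
                       feature_vars = c("dl_norm", "dp_norm", "dtheta",
                                        "dalpha", "dgamma")) {
  if (nrow(transitions) == 0) return(transitions)
  keep <- rep(TRUE, nrow(transitions))
  key <- interaction(transitions$category, transitions$participant,
                     transitions$lap, transitions$instance, drop = TRUE)
  for (cat in unique(transitions$category)) {
    rows <- which(transitions$category == cat)
    ids <- unique(key[rows])
    if (length(ids) < 4) {
      warning(sprintf("category '%s' has %d instance(s) (< 4); IQR filter skipped",
                      cat, length(ids)))
      next
    }
    flagged <- character(0)
    for (v in feature_vars) for (ri in unique(transitions$rel_index[rows])) {
      cell <- rows[transitions$rel_index[rows] == ri]
      x <- transitions[[v]][cell]
      q <- stats::quantile(x, c(0.25, 0.75), type = 7, names = FALSE)
      iqr <- q[2] - q[1]
      bad <- x < q[1] - 1.5 * iqr | x > q[2] + 1.5 * iqr
      flagged <- union(flagged, as.character(key[cell][bad]))
    }
    keep[rows][key[rows] %in% flagged] <- FALSE
  }
  transitions[keep, , drop = FALSE]
}
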