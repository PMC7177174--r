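#' @title The simulated rater
#'
#' @description Orchestrates the workflow a radiologist would follow with an
#' interactive segmentation engine: pick the axial slice where the lesion
#' looks largest, draw a long axis by one of four strategies, optionally add
#' the perpendicular short axis, drop boundary points where the real-time 2D
#' result disagrees with ground truth, open the MPR trio through the axis
#' midpoint and repeat on the coronal and sagittal planes, optionally edit
#' plane contours to perfection, and finally run 3D segmentation. Everything
#' is deterministic given the configuration, and every action is recorded in
#' a replayable trace.
#' @name interaction
NULL

#' Interaction levels
#'
#' Eight levels crossing the amount of in-plane interaction (long axis only;
#' long + short axes; long + short + dropped points; edited to perfection)
#' with the plane scope (axial only vs all three MPR planes).
#' @export
interaction_levels <- function() {
  c("LONG_AXIAL", "LONG_SHORT_AXIAL", "LONG_SHORT_DROPS_AXIAL",
    "PERFECT_AXIAL", "LONG_MPR", "LONG_SHORT_MPR", "LONG_SHORT_DROPS_MPR",
    "PERFECT_MPR")
}

level_flags <- function(level) {
  level <- match.arg(level, interaction_levels())
  list(level = level,
       mpr = grepl("MPR$", level),
       short = grepl("SHORT", level),
       drops = grepl("DROPS", level),
       perfect = grepl("PERFECT", level))
}

#' Dropped-point policy
#'
#' @param min_spacing_px Minimum pairwise distance between dropped points;
#'   new points cannot be placed too close to earlier ones.
#' @param disagreement_threshold_px Minimum boundary disagreement worth
#'   fixing; below it, no more points are dropped.
#' @param max_drops Cap on drops per plane.
#' @return A `drop_policy` list.
#' @export
drop_policy <- function(min_spacing_px = 5, disagreement_threshold_px = 2,
                        max_drops = 5L) {
  stopifnot(min_spacing_px > 0, disagreement_threshold_px > 0, max_drops >= 0)
  structure(list(min_spacing_px = min_spacing_px,
                 disagreement_threshold_px = disagreement_threshold_px,
                 max_drops = as.integer(max_drops)),
            class = "drop_policy")
}

#' Ground-truth boundary point of greatest disagreement
#'
#' Finds the ground-truth boundary point farthest from the segmentation
#' boundary — where a user would click to correct the contour. Points within
#' `min_spacing_px` of an existing drop are ineligible; `NULL` is returned
#' when the largest remaining disagreement is below
#' `disagreement_threshold_px` or no eligible point remains.
#'
#' @param seg2d,gt2d 2D segmentation and ground-truth masks.
#' @param existing `n x 2` matrix of earlier drops, or `NULL`.
#' @param policy A [drop_policy()].
#' @return Length-2 `(row, col)` point, or `NULL`.
#' @export
worst_disagreement_point <- function(seg2d, gt2d, existing = NULL,
                                     policy = drop_policy()) {
  if (!any(gt2d)) return(NULL)
  G <- boundary_points(gt2d)
  S <- if (any(seg2d)) boundary_points(seg2d) else cbind(numeric(0), numeric(0))
  disagreement <- min_dist_to_set(G, S)
  eligible <- rep(TRUE, nrow(G))
  if (!is.null(existing) && nrow(rbind(existing)) > 0)
    eligible <- min_dist_to_set(G, rbind(existing)) >= policy$min_spacing_px
  if (!any(eligible)) return(NULL)
  disagreement[!eligible] <- -Inf
  best <- which.max(disagreement)
  if (disagreement[best] < policy$disagreement_threshold_px) return(NULL)
  G[best, ]
}

#' Iteratively drop points and re-segment
#'
#' Repeats: find the worst disagreement point, drop it, trigger a new
#' segmentation — until no significant disagreement remains or `max_drops`
#' is reached.
#'
#' @param seg2d Current 2D segmentation.
#' @param gt2d Ground-truth cross-section.
#' @param resegment `function(drops_matrix) -> 2D mask`, typically a closure
#'   over the engine and the accumulated axes.
#' @param policy A [drop_policy()].
#' @param existing Earlier drops (`n x 2` matrix), or `NULL`.
#' @return List with `mask` (final 2D mask) and `drops` (all drops placed,
#'   `n x 2` matrix, possibly empty).
#' @export
drop_points_loop <- function(seg2d, gt2d, resegment, policy = drop_policy(),
                             existing = NULL) {
  drops <- if (is.null(existing)) matrix(numeric(0), 0, 2) else rbind(existing)
  mask <- seg2d
  n0 <- nrow(drops)
  while (nrow(drops) - n0 < policy$max_drops) {
    p <- worst_disagreement_point(mask, gt2d, drops, policy)
    if (is.null(p)) break
    drops <- rbind(drops, p)
    mask <- tryCatch(resegment(drops), error = function(e) {
      warning("re-segmentation after drop failed: ", conditionMessage(e))
      mask
    })
  }
  list(mask = mask, drops = drops)
}

#' Replace plane contours with ground truth
#'
#' The strongest editing level: each in-scope plane mask is replaced by the
#' ground-truth cross-section on that plane (the 3D stage is then re-run by
#' the caller from the corrected planes).
#'
#' @param state A `seg_state` whose `plane_index` covers the target planes.
#' @param gt Ground-truth 3D mask.
#' @param planes Planes to correct, subset of axial/coronal/sagittal.
#' @return The updated `seg_state`.
#' @export
edit_to_perfection <- function(state, gt,
                               planes = c("axial", "coronal", "sagittal")) {
  for (plane in planes) {
    idx <- state$plane_index[[plane]]
    if (is.null(idx) || is.na(idx)) next
    gp <- extract_plane(gt, plane, idx)$data
    state$plane_masks[[plane]] <- gp != 0
    state$interaction[[plane]] <- interaction_input(replace_mask = gp != 0)
  }
  state
}

## Draw a long axis on a ground-truth cross-section by strategy name.
draw_long_axis <- function(strategy, gt2d, img2d, engine,
                           params = axis_score_params(), spacing = c(1, 1)) {
  switch(match.arg(strategy, c("true_longest", "medial", "statistical", "swept")),
         true_longest = true_longest_axis(gt2d, spacing),
         medial = medial_long_axis(gt2d, spacing = spacing),
         statistical = statistical_axis_search(gt2d, img2d, params, spacing),
         swept = sweep_axis(true_longest_axis(gt2d, spacing), gt2d, img2d,
                            engine, gt2d, params, spacing))
}

#' Simulation configuration
#'
#' @param params [axis_score_params()].
#' @param policy [drop_policy()].
#' @return A `sim_config` list.
#' @export
sim_config <- function(params = axis_score_params(), policy = drop_policy()) {
  structure(list(params = params, policy = policy), class = "sim_config")
}

#' Simulate the interactive segmentation of one lesion
#'
#' Runs the full simulated workflow at one interaction level with one
#' long-axis strategy, and returns the final 3D mask together with a
#' replayable interaction trace and per-stage Dice scores.
#'
#' @param vol [scalar_volume] being segmented.
#' @param lesion A `lesion_record` (the ground truth for this lesion).
#' @param level One of [interaction_levels()].
#' @param strategy `"true_longest"`, `"medial"`, `"statistical"` or
#'   `"swept"`.
#' @param engine A `seg_engine` (default: the reference engine).
#' @param config A [sim_config()].
#' @param seed Recorded in the trace for bookkeeping; the pipeline itself is
#'   deterministic.
#' @return List with `mask` (3D logical), `trace` (class
#'   `interaction_trace`), `stage_dsc` (named: `d2`, `scout`, `d3`), and
#'   `state` (the final `seg_state`).
#' @export
simulate_lesion <- function(vol, lesion, level = "LONG_AXIAL",
                            strategy = "true_longest",
                            engine = make_engine(), config = sim_config(),
                            seed = NULL) {
  if (lesion$voxel_count == 0L) stop("empty lesion", call. = FALSE)
  fl <- level_flags(level)
  params <- config$params; policy <- config$policy
  k <- select_axial_slice(lesion)
  pl_img <- extract_plane(vol, "axial", k)
  img_ax <- pl_img$data
  sp2 <- pl_img$spacing
  gt_ax <- extract_plane(lesion$mask, "axial", k)$data
  actions <- list()
  long <- draw_long_axis(strategy, gt_ax, img_ax, engine, params, sp2)
  actions <- c(actions, list(list(type = "long_axis", plane = "axial",
                                  strategy = strategy, p0 = long$p0,
                                  p1 = long$p1)))
  axes <- list(long)
  if (fl$short) {
    sh <- short_axis(gt_ax, long, sp2)
    if (sh$length_mm > 0) {
      axes <- c(axes, list(sh))
      actions <- c(actions, list(list(type = "short_axis", plane = "axial",
                                      p0 = sh$p0, p1 = sh$p1)))
    }
  }
  inter_ax <- interaction_input(axes = axes)
  seg2 <- engine$segment_2d(img_ax, inter_ax, sp2)
  if (fl$drops) {
    res <- drop_points_loop(seg2, gt_ax, function(dr)
      engine$segment_2d(img_ax, interaction_input(axes = axes, drops = dr),
                        sp2), policy)
    seg2 <- res$mask
    inter_ax <- interaction_input(axes = axes, drops = res$drops)
    if (nrow(res$drops) > 0)
      actions <- c(actions, lapply(seq_len(nrow(res$drops)), function(i)
        list(type = "drop", plane = "axial", point = res$drops[i, ])))
  }
  mid3 <- plane_to3d(pl_img, axis_midpoint(long))
  state <- seg_state("2d", plane_masks = list(axial = seg2),
                     plane_index = c(axial = k), mid3 = mid3,
                     interaction = list(axial = inter_ax))
  if (fl$perfect) {
    state$plane_masks$axial <- gt_ax
    state$interaction$axial <- interaction_input(axes = axes,
                                                 replace_mask = gt_ax)
    actions <- c(actions, list(list(type = "edit_to_perfection",
                                    plane = "axial")))
  }
  d2 <- dsc(state$plane_masks$axial, gt_ax)
  # MPR interaction on the reformatted planes through the axis midpoint
  d <- dim(vol_data(vol))
  mid3r <- clamp(round(mid3), 1, d)
  plane_idx <- c(coronal = unname(mid3r[2]), sagittal = unname(mid3r[1]))
  mpr_inter <- list()
  if (fl$mpr) {
    for (plane in c("coronal", "sagittal")) {
      gt_pl <- extract_plane(lesion$mask, plane, plane_idx[[plane]])
      gt_p <- gt_pl$data != 0
      if (fl$perfect) {
        mpr_inter[[plane]] <- interaction_input(replace_mask = gt_p)
        actions <- c(actions, list(list(type = "edit_to_perfection",
                                        plane = plane)))
        next
      }
      if (!any(gt_p)) next
      img_p <- extract_plane(vol, plane, plane_idx[[plane]])
      long_p <- draw_long_axis(strategy, gt_p, img_p$data, engine, params,
                               img_p$spacing)
      axes_p <- list(long_p)
      actions <- c(actions, list(list(type = "long_axis", plane = plane,
                                      strategy = strategy, p0 = long_p$p0,
                                      p1 = long_p$p1)))
      if (fl$short) {
        sh_p <- short_axis(gt_p, long_p, img_p$spacing)
        if (sh_p$length_mm > 0) {
          axes_p <- c(axes_p, list(sh_p))
          actions <- c(actions, list(list(type = "short_axis", plane = plane,
                                          p0 = sh_p$p0, p1 = sh_p$p1)))
        }
      }
      mpr_inter[[plane]] <- interaction_input(axes = axes_p)
    }
  }
  scout <- engine$segment_scout(vol, state, mpr_inter)
  if (fl$mpr && fl$drops) {
    for (plane in c("coronal", "sagittal")) {
      inter_p <- scout$interaction[[plane]] %||% interaction_input()
      if (length(inter_p$axes) == 0L) next
      gt_p <- extract_plane(lesion$mask, plane, plane_idx[[plane]])$data != 0
      res <- drop_points_loop(scout$plane_masks[[plane]], gt_p, function(dr) {
        ip <- inter_p; ip$drops <- dr
        engine$resegment_plane(vol, scout, plane, ip)
      }, policy)
      if (nrow(res$drops) > 0) {
        scout$plane_masks[[plane]] <- res$mask
        inter_p$drops <- res$drops
        scout$interaction[[plane]] <- inter_p
        actions <- c(actions, lapply(seq_len(nrow(res$drops)), function(i)
          list(type = "drop", plane = plane, point = res$drops[i, ])))
      }
    }
  }
  scout_dsc <- mean(vapply(names(scout$plane_masks), function(plane) {
    gp <- extract_plane(lesion$mask, plane,
                        scout$plane_index[[plane]])$data != 0
    dsc(scout$plane_masks[[plane]], gp)
  }, 0))
  final <- engine$segment_3d(vol, scout)
  d3 <- dsc(final$volume_mask, lesion$mask)
  trace <- structure(list(lesion_id = lesion$lesion_id, level = fl$level,
                          strategy = strategy, seed = seed,
                          axial_slice = k, mid3 = mid3,
                          actions = actions,
                          interaction = list(axial = state$interaction$axial,
                                             coronal = scout$interaction$coronal,
                                             sagittal = scout$interaction$sagittal)),
                     class = "interaction_trace")
  list(mask = final$volume_mask, trace = trace,
       stage_dsc = c(d2 = d2, scout = scout_dsc, d3 = d3),
       state = final)
}

#' @export
print.interaction_trace <- function(x, ...) {
  cat(sprintf("<interaction_trace> lesion %s, %s / %s: %d action(s)\n",
              x$lesion_id, x$level, x$strategy, length(x$actions)))
  for (a in x$actions)
    cat(sprintf("  - %s [%s]\n", a$type, a$plane))
  invisible(x)
}

#' Replay an interaction trace through the engine
#'
#' Re-runs the engine stages using the recorded interactions (no strategy
#' search), reproducing the final mask bit-exactly.
#'
#' @param vol The [scalar_volume] used originally.
#' @param trace An `interaction_trace` from [simulate_lesion()].
#' @param engine The engine to replay through.
#' @return The final 3D logical mask.
#' @export
replay_trace <- function(vol, trace, engine = make_engine()) {
  k <- trace$axial_slice
  pl_img <- extract_plane(vol, "axial", k)
  inter_ax <- trace$interaction$axial
  if (!is.null(inter_ax$replace_mask)) {
    seg2 <- inter_ax$replace_mask
  } else {
    seg2 <- engine$segment_2d(pl_img$data, inter_ax, pl_img$spacing)
  }
  state <- seg_state("2d", plane_masks = list(axial = seg2),
                     plane_index = c(axial = k), mid3 = trace$mid3,
                     interaction = list(axial = inter_ax))
  mpr_inter <- list(coronal = trace$interaction$coronal,
                    sagittal = trace$interaction$sagittal)
  mpr_inter <- mpr_inter[!vapply(mpr_inter, is.null, TRUE)]
  scout <- engine$segment_scout(vol, state, mpr_inter)
  final <- engine$segment_3d(vol, scout)
  final$volume_mask
}

#' Simulate all lesions of a patient and unite the results
#'
#' Lesions are segmented individually and the per-lesion masks united, so
#' the aggregate can be scored against a per-patient ground truth. Per-lesion
#' failures are excluded from the union and reported.
#'
#' @param vol [scalar_volume].
#' @param lesions List of `lesion_record`s (from [enumerate_lesions()]).
#' @param level,strategy,engine,config,seed As in [simulate_lesion()].
#' @return List with `mask` (union), `traces`, `stage_dsc` (matrix, one row
#'   per lesion), `failures` (list of error records).
#' @export
simulate_patient <- function(vol, lesions, level = "LONG_AXIAL",
                             strategy = "true_longest",
                             engine = make_engine(), config = sim_config(),
                             seed = NULL) {
  if (length(lesions) == 0L) stop("at least one lesion required", call. = FALSE)
  d <- dim(vol_data(vol))
  un <- array(FALSE, d)
  traces <- list(); failures <- list()
  stage <- matrix(NA_real_, length(lesions), 3,
                  dimnames = list(NULL, c("d2", "scout", "d3")))
  for (i in seq_along(lesions)) {
    res <- tryCatch(simulate_lesion(vol, lesions[[i]], level, strategy,
                                    engine, config, seed),
                    error = function(e)
                      structure(list(message = conditionMessage(e)),
                                class = "lesion_failure"))
    if (inherits(res, "lesion_failure")) {
      failures <- c(failures, list(list(lesion_id = lesions[[i]]$lesion_id,
                                        error = res$message)))
      next
    }
    un <- un | res$mask
    traces <- c(traces, list(res$trace))
    stage[i, ] <- res$stage_dsc
  }
  list(mask = un, traces = traces, stage_dsc = stage, failures = failures)
}
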