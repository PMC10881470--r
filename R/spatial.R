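#' Known cell phenotype labels
#' @return character vector of the closed phenotype vocabulary.
#' @export
cell_phenotypes <- function() c("panCK", "CD8", "FoxP3", "CD4", "other")

validate_cells <- function(cells) {
  stopifnot(is.data.frame(cells), all(c("x_um", "y_um", "phenotype") %in% names(cells)))
  if (any(!is.finite(cells$x_um)) || any(!is.finite(cells$y_um)))
    stop_icistrat("cell coordinates must be finite")
  bad <- setdiff(unique(cells$phenotype), cell_phenotypes())
  if (length(bad))
    stop_icistrat("unknown phenotype label(s): %s", paste(bad, collapse = ", "))
  cells
}

#' Reconstruct the panCK+ tumor region from a cell table
#'
#' The tumor region is modeled as the union of disks of radius `r` centered
#' at the panCK+ cells (the pipeline ingests cell tables, not images, so a
#' morphological reconstruction from tumor-cell centroids stands in for a
#' pixel-classifier mask).
#'
#' @param cells data.frame with `x_um`, `y_um`, `phenotype`.
#' @param r disk radius in micrometers (> 0), default 20.
#' @return object of class `tumor_region` holding the panCK centers and `r`;
#'   empty (with a warning) when there are no panCK cells.
#' @export
build_tumor_region <- function(cells, r = 20) {
  if (r <= 0) stop_icistrat("disk radius must be > 0")
  cells <- validate_cells(cells)
  ck <- cells[cells$phenotype == "panCK", c("x_um", "y_um"), drop = FALSE]
  if (!nrow(ck)) warn_icistrat("no panCK cells: tumor region is empty")
  structure(list(centers = as.matrix(ck), r = r), class = "tumor_region")
}

#' Is a tumor region empty?
#' @param region a `tumor_region`.
#' @return logical.
#' @export
is_empty_region <- function(region) {
  stopifnot(inherits(region, "tumor_region"))
  nrow(region$centers) == 0L
}

# distance from points (matrix nx2) to the region boundary; 0 inside
region_distance <- function(region, pts) {
  stopifnot(inherits(region, "tumor_region"))
  if (is_empty_region(region)) return(rep(NA_real_, nrow(pts)))
  d <- vapply(seq_len(nrow(pts)), function(i) {
    dx <- region$centers[, 1L] - pts[i, 1L]
    dy <- region$centers[, 2L] - pts[i, 2L]
    sqrt(min(dx * dx + dy * dy))
  }, 0)
  pmax(0, d - region$r)
}

#' Point-in-region membership test
#' @param region a `tumor_region`.
#' @param x,y coordinates (vectorized).
#' @return logical vector; consistent with [ctl_tumor_distance()] distance 0.
#' @export
point_in_region <- function(region, x, y) {
  region_distance(region, cbind(x, y)) == 0
}

#' CTL-to-tumor-region distances
#'
#' For every CD8+ cell, the Euclidean distance to the tumor region boundary
#' (`max(0, min distance to a panCK center - r)`); cells inside the region
#' score 0 ("infiltrated"). The per-sample summary statistic is the median.
#'
#' @param cells cell table (needs CD8 rows).
#' @param region a non-empty [build_tumor_region()] result.
#' @return list with `distances` (per CD8 cell, micrometers) and `median`.
#' @export
ctl_tumor_distance <- function(cells, region) {
  cells <- validate_cells(cells)
  if (is_empty_region(region)) {
    warn_icistrat("empty tumor region: CTL-tumor distances undefined")
    return(list(distances = NULL, median = NA_real_))
  }
  cd8 <- cells[cells$phenotype == "CD8", c("x_um", "y_um"), drop = FALSE]
  if (!nrow(cd8)) {
    warn_icistrat("no CD8 cells: CTL-tumor distance missing")
    return(list(distances = NULL, median = NA_real_))
  }
  d <- region_distance(region, as.matrix(cd8))
  list(distances = d, median = median(d))
}

#' CTL-to-nearest-Treg distances
#'
#' For every CD8+ cell, the Euclidean distance to the nearest FoxP3+ cell
#' (the proximity of the closest suppressor is the biologically relevant
#' quantity). The per-sample summary is the median.
#'
#' @param cells cell table (needs CD8 and FoxP3 rows).
#' @return list with `distances` and `median`; missing with a warning when a
#'   phenotype is absent.
#' @export
ctl_treg_distance <- function(cells) {
  cells <- validate_cells(cells)
  cd8 <- as.matrix(cells[cells$phenotype == "CD8", c("x_um", "y_um"), drop = FALSE])
  treg <- as.matrix(cells[cells$phenotype == "FoxP3", c("x_um", "y_um"), drop = FALSE])
  if (!nrow(cd8) || !nrow(treg)) {
    warn_icistrat("missing CD8 or FoxP3 cells: CTL-Treg distance undefined")
    return(list(distances = NULL, median = NA_real_))
  }
  d <- vapply(seq_len(nrow(cd8)), function(i) {
    dx <- treg[, 1L] - cd8[i, 1L]; dy <- treg[, 2L] - cd8[i, 2L]
    sqrt(min(dx * dx + dy * dy))
  }, 0)
  list(distances = d, median = median(d))
}

#' Call a treatment-induced distance shift
#'
#' Two-sided Mann-Whitney test on per-cell distances between arms; the call
#' is `no_change` when p >= alpha, otherwise `significant_increase` or
#' `significant_decrease` by the sign of (treated median - control median).
#'
#' @param distances_control,distances_treated per-cell distances (>= 3 each).
#' @param alpha significance level, default 0.05.
#' @return list with `statistic`, `p`, `call`, and the two medians.
#' @export
distance_shift_call <- function(distances_control, distances_treated, alpha = 0.05) {
  if (length(distances_control) < 3L || length(distances_treated) < 3L)
    stop_icistrat("need >= 3 distances per arm")
  test <- compare_groups(distances_treated, distances_control, paired = FALSE)
  delta <- median(distances_treated) - median(distances_control)
  call <- if (test$p >= alpha || delta == 0) "no_change"
          else if (delta > 0) "significant_increase" else "significant_decrease"
  list(statistic = test$statistic, p = test$p, call = call,
       median_control = median(distances_control),
       median_treated = median(distances_treated))
}

#' Count cells per phenotype
#' @param cells cell table.
#' @return named integer vector over [cell_phenotypes()].
#' @export
count_phenotypes <- function(cells) {
  cells <- validate_cells(cells)
  vapply(cell_phenotypes(), function(p) sum(cells$phenotype == p), 0L)
}

#' Per-sample spatial summary across arms
#'
#' Computes, for each (sample, arm) cell table: phenotype counts, the median
#' CTL-tumor distance, the median CTL-Treg distance, and for each treated arm
#' the CTL-tumor distance shift call versus control.
#'
#' @param cells long cell table with `sample_id`, `arm`, `x_um`, `y_um`,
#'   `phenotype`.
#' @param r tumor-region disk radius (micrometers).
#' @param alpha significance level for shift calls.
#' @param control_arm name of the control arm, default `"Control"`.
#' @return data.frame, one row per (sample, arm), with counts, medians and
#'   `ctl_tumor_shift` call (`NA` for the control arm).
#' @export
spatial_summary <- function(cells, r = 20, alpha = 0.05, control_arm = "Control") {
  stopifnot(all(c("sample_id", "arm") %in% names(cells)))
  validate_cells(cells)
  out <- list()
  for (sid in unique(cells$sample_id)) {
    sc <- cells[cells$sample_id == sid, , drop = FALSE]
    arms <- unique(sc$arm)
    per_arm <- lapply(arms, function(a) {
      ac <- sc[sc$arm == a, , drop = FALSE]
      region <- build_tumor_region(ac, r)
      list(counts = count_phenotypes(ac),
           ctl_tumor = ctl_tumor_distance(ac, region),
           ctl_treg = suppressWarnings(ctl_treg_distance(ac)))
    })
    names(per_arm) <- arms
    for (a in arms) {
      pa <- per_arm[[a]]
      shift <- NA_character_; shift_p <- NA_real_
      if (a != control_arm && control_arm %in% arms) {
        d0 <- per_arm[[control_arm]]$ctl_tumor$distances
        d1 <- pa$ctl_tumor$distances
        if (length(d0) >= 3L && length(d1) >= 3L) {
          call <- distance_shift_call(d0, d1, alpha)
          shift <- call$call; shift_p <- call$p
        }
      }
      out[[paste(sid, a)]] <- data.frame(
        sample_id = sid, arm = a,
        n_panCK = pa$counts[["panCK"]], n_CD8 = pa$counts[["CD8"]],
        n_FoxP3 = pa$counts[["FoxP3"]],
        median_ctl_tumor_um = pa$ctl_tumor$median,
        median_ctl_treg_um = pa$ctl_treg$median,
        ctl_tumor_shift = shift, shift_p = shift_p,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
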