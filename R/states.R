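#' Reported RPE cell and nucleus dimensions per condition
#'
#' Mean cell/nucleus heights, widths (average of min and max Feret diameters
#' of the z-projection) and volumes for iPSC-derived RPE monolayers matured
#' for 1-4 weeks under PGE2 (promotes apical-basal polarization) or HPI4
#' (blocks it). Week 1 is the shared starting point of both arms. Values are
#' dataset-level means in um / um^3; entries not reported for a given week are
#' `NA` and are linearly interpolated by [condition_state()].
#'
#' These numbers parameterize the default phantom states, and the week-1
#' volumes give the worked-example cytoplasm-to-nucleus ratio shown in the
#' README.
#'
#' @return A data.frame with one row per treatment x week.
#' @export
rpe_reference_dims <- function() {
  data.frame(
    treatment = rep(c("PGE2", "HPI4"), each = 4L),
    week = rep(1:4, 2L),
    cell_height    = c(4.6, 5.9,  NA, 5.3,   4.6, 4.0,  NA, 3.5),
    cell_width     = c(19.1, 15.9, NA, 17.1, 19.1, 18.9, NA, 21.8),
    nucleus_height = c(4.6, 5.3, 4.8, 4.8,   4.6, 3.5, 3.2, 3.2),
    nucleus_width  = c(11.6, 9.5, 9.5, 9.5,  11.6, 10.9, 11.3, 11.3),
    cell_volume    = c(813.5, NA, 776.7, 776.7, 813.5, NA, NA, 925.0),
    nucleus_volume = c(377.9, NA, NA, 257.2,  377.9, NA, NA, 279.2),
    stringsAsFactors = FALSE
  )
}

#' Default organelle class table for the phantom generator
#'
#' Sixteen GFP-taggable intracellular structures with the geometric archetype
#' used to draw them (spot, blob, filament, shell), the lateral/axial
#' placement law, the mean object count per cell and mean single-object
#' volume (um^3). Counts and volumes are generator defaults chosen to be
#' realistic for RPE-scale cells; they are not measured values. LMNB1 is the
#' nuclear envelope and is drawn as a shell around the nucleus (no shape
#' metrics are computed for it downstream).
#'
#' Placement laws:
#' \describe{
#'   \item{apical-central}{centroids above the parent-nucleus centroid plane
#'     and within half the lateral radius of the cell centre (e.g. lysosomes
#'     in polarized cells).}
#'   \item{perinuclear}{centroids in a shell hugging the nucleus border.}
#'   \item{lateral-dispersed}{uniform across the cell interior.}
#'   \item{border-bound}{against the lateral cell border (junction proteins).}
#' }
#'
#' @return A data.frame with one row per structure class.
#' @export
organelle_class_defaults <- function() {
  df <- read.csv(text =
"class,archetype,placement,count_mean,object_volume_mean
LAMP1,spot,apical-central,20,0.45
RAB5A,spot,lateral-dispersed,25,0.15
SLC25A17,spot,lateral-dispersed,30,0.10
CETN2,spot,apical-central,2,0.08
FBL,spot,perinuclear,3,0.60
ST6GAL1,blob,perinuclear,5,2.0
TOMM20,filament,perinuclear,15,1.2
SEC61B,filament,perinuclear,12,1.5
TUBA1B,filament,lateral-dispersed,10,1.0
ACTB,filament,border-bound,12,1.0
MYH10,filament,border-bound,10,0.8
CTNNB1,spot,border-bound,18,0.12
TJP1,spot,border-bound,18,0.10
GJA1,spot,border-bound,12,0.10
DSP,spot,border-bound,15,0.08
LMNB1,shell,perinuclear,1,25
", stringsAsFactors = FALSE)
  df
}

#' Construct a polarity state for the phantom generator
#'
#' A polarity state bundles the geometry a synthetic monolayer is drawn from:
#' cell and nucleus height/width means and per-cell jitter SDs, plus the
#' organelle class table. Named presets use the reported week-4 dimensions of
#' the two treatment arms (`"polarized"` = PGE2 week 4: 5.3 um tall, 17.1 um
#' wide; `"nonpolarized"` = HPI4 week 4: 3.5 um tall, 21.8 um wide) and week 1
#' for `"baseline"` (4.6 um, 19.1 um). A numeric `p` in \[0, 1\] interpolates
#' linearly from nonpolarized (0) to polarized (1).
#'
#' Per-cell jitter SDs default to 0.4 um (height) and 1.2 um (width),
#' realistic single-cell spreads for an epithelial monolayer; the reported
#' dataset-level SDs are much smaller because they average thousands of cells.
#'
#' @param label `"baseline"`, `"polarized"`, `"nonpolarized"`, or a number in
#'   \[0, 1\] (degree of polarization).
#' @param cell_height_sd,cell_width_sd per-cell jitter SDs in um.
#' @param organelles organelle class table; see [organelle_class_defaults()].
#' @param ... override any field (e.g. `cell_height_mean = 6`).
#' @return An object of class `polarity_state`.
#' @examples
#' polarity_state("polarized")
#' polarity_state(0.5)$cell_height_mean
#' @export
polarity_state <- function(label = "baseline",
                           cell_height_sd = 0.4, cell_width_sd = 1.2,
                           organelles = organelle_class_defaults(), ...) {
  dims <- rpe_reference_dims()
  pick <- function(tr, wk) dims[dims$treatment == tr & dims$week == wk, ]
  pol <- pick("PGE2", 4L); non <- pick("HPI4", 4L); base <- pick("PGE2", 1L)
  if (is.numeric(label)) {
    p <- label
    if (length(p) != 1L || !is.finite(p) || p < 0 || p > 1)
      stop("numeric polarity must be a single value in [0, 1]")
    mix <- function(f) (1 - p) * non[[f]] + p * pol[[f]]
    row <- non
    for (f in c("cell_height", "cell_width", "nucleus_height", "nucleus_width"))
      row[[f]] <- mix(f)
    lab <- sprintf("p=%.2f", p)
  } else {
    lab <- match.arg(label, c("baseline", "polarized", "nonpolarized"))
    row <- switch(lab, baseline = base, polarized = pol, nonpolarized = non)
  }
  st <- list(
    label = lab,
    cell_height_mean = row$cell_height, cell_height_sd = cell_height_sd,
    cell_width_mean = row$cell_width, cell_width_sd = cell_width_sd,
    nucleus_height_mean = row$nucleus_height,
    nucleus_width_mean = row$nucleus_width,
    # nucleus centre as a fraction of cell height (nuclei sit mid/basally)
    nucleus_center_frac = 0.45,
    organelles = organelles
  )
  dots <- list(...)
  st[names(dots)] <- dots
  bad <- c(st$cell_height_mean, st$cell_width_mean,
           st$nucleus_height_mean, st$nucleus_width_mean)
  if (any(!is.finite(bad)) || any(bad <= 0))
    stop("state heights/widths must be positive")
  structure(st, class = "polarity_state")
}

#' @export
print.polarity_state <- function(x, ...) {
  cat(sprintf("polarity state '%s': cell %.2f x %.2f um, nucleus %.2f x %.2f um, %d organelle classes\n",
              x$label, x$cell_height_mean, x$cell_width_mean,
              x$nucleus_height_mean, x$nucleus_width_mean,
              nrow(x$organelles)))
  invisible(x)
}

#' Polarity state for a given treatment arm and week
#'
#' Looks up the reported cell/nucleus dimensions for a treatment x week
#' condition (linearly interpolating the weeks without a reported value) and
#' returns the corresponding phantom state.
#'
#' @param treatment `"PGE2"` or `"HPI4"`.
#' @param week integer 1-4.
#' @param ... passed to [polarity_state()] overrides.
#' @return A `polarity_state`.
#' @export
condition_state <- function(treatment = c("PGE2", "HPI4"), week = 1, ...) {
  treatment <- match.arg(treatment)
  if (!week %in% 1:4) stop("week must be in 1..4")
  d <- rpe_reference_dims()
  d <- d[d$treatment == treatment, ]
  fill <- function(v) {
    if (anyNA(v)) v <- stats::approx(d$week[!is.na(v)], v[!is.na(v)],
                                     xout = d$week, rule = 2)$y
    v
  }
  st <- polarity_state("baseline", ...)
  st$label <- sprintf("%s_week%d", treatment, week)
  st$cell_height_mean <- fill(d$cell_height)[week]
  st$cell_width_mean <- fill(d$cell_width)[week]
  st$nucleus_height_mean <- fill(d$nucleus_height)[week]
  st$nucleus_width_mean <- fill(d$nucleus_width)[week]
  st
}
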