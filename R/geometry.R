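#' Apparatus geometry for a three-chamber social-interaction arena
#'
#' Describes the calibrated overhead-view layout of the arena in centimetres:
#' the positions and footprint radius of the two conspecific cages, the
#' interaction zone around each cage, and the radial bands used to classify
#' sniffing ("lower section" of the cage, seen from above as a perimeter
#' annulus) and rearing ("upper section", seen from above as the cage
#' footprint itself).
#'
#' All lengths are in cm; `px_per_cm` converts raw pixel coordinates from the
#' pose estimator into this frame. The coordinate convention is overhead-view
#' 2D with the origin at the top-left of the image and y increasing downward.
#'
#' @param px_per_cm Pixels per centimetre of the overhead camera (> 0).
#' @param arena_w_cm,arena_h_cm Arena bounding rectangle, cm.
#' @param cage_a_center,cage_b_center Numeric length-2 cage centers `c(x, y)`, cm.
#' @param cage_radius_cm Radius of the circular cage footprint in overhead
#'   view, cm.
#' @param interaction_radius_cm Distance from the cage footprint boundary
#'   within which a frame counts as interaction (default 5 cm).
#' @param sniff_band_cm Width of the perimeter annulus outside the footprint
#'   classified as sniffing (default 3 cm; must not exceed
#'   `interaction_radius_cm`).
#' @param rear_inset_cm Depth inside the footprint required for the snout to
#'   count as rearing (default 0: any snout over the footprint).
#' @param rear_fallback_cm Mid-body distance-to-boundary threshold used to
#'   infer rearing when the snout fails the confidence gate (default
#'   `cage_radius_cm + 2`).
#' @param confidence_threshold Landmark likelihood gate in `[0, 1]`
#'   (default 0.6).
#' @param fps Frame rate of the recording, frames/second (default 25).
#'
#' @return An object of class `apparatus_geometry`.
#' @export
#' @examples
#' geom <- apparatus_geometry(px_per_cm = 8)
#' geom$interaction_radius_cm
apparatus_geometry <- function(px_per_cm = 1,
                               arena_w_cm = 60, arena_h_cm = 40,
                               cage_a_center = c(10, 20),
                               cage_b_center = c(50, 20),
                               cage_radius_cm = 5,
                               interaction_radius_cm = 5,
                               sniff_band_cm = 3,
                               rear_inset_cm = 0,
                               rear_fallback_cm = cage_radius_cm + 2,
                               confidence_threshold = 0.6,
                               fps = 25) {
  stopifnot(is.numeric(px_per_cm), px_per_cm > 0,
            arena_w_cm > 0, arena_h_cm > 0,
            length(cage_a_center) == 2, length(cage_b_center) == 2,
            cage_radius_cm > 0, interaction_radius_cm >= 0,
            sniff_band_cm >= 0, rear_inset_cm >= 0, rear_fallback_cm >= 0,
            confidence_threshold >= 0, confidence_threshold <= 1, fps > 0)
  if (sniff_band_cm > interaction_radius_cm) {
    stop("sniff_band_cm must not exceed interaction_radius_cm ",
         "(the sniff band must lie inside the interaction zone)")
  }
  geom <- structure(list(
    px_per_cm = px_per_cm,
    arena_w_cm = arena_w_cm, arena_h_cm = arena_h_cm,
    cage_a_center = as.numeric(cage_a_center),
    cage_b_center = as.numeric(cage_b_center),
    cage_radius_cm = cage_radius_cm,
    interaction_radius_cm = interaction_radius_cm,
    sniff_band_cm = sniff_band_cm,
    rear_inset_cm = rear_inset_cm,
    rear_fallback_cm = rear_fallback_cm,
    confidence_threshold = confidence_threshold,
    fps = fps
  ), class = "apparatus_geometry")
  validate_geometry(geom)
  geom
}

validate_geometry <- function(geom) {
  for (cc in list(geom$cage_a_center, geom$cage_b_center)) {
    if (cc[1] < 0 || cc[1] > geom$arena_w_cm ||
        cc[2] < 0 || cc[2] > geom$arena_h_cm) {
      stop("cage center ", paste(cc, collapse = ","),
           " lies outside the arena bounds")
    }
  }
  # interaction zones (footprint + interaction radius) must not overlap,
  # otherwise nearest-cage assignment is ill-posed
  sep <- sqrt(sum((geom$cage_a_center - geom$cage_b_center)^2))
  zone <- geom$cage_radius_cm + geom$interaction_radius_cm
  if (sep <= 2 * zone) {
    stop("cage interaction zones overlap: centers ", round(sep, 2),
         " cm apart but each zone extends ", zone, " cm")
  }
  invisible(geom)
}

#' Calibrate apparatus geometry from annotated reference points
#'
#' Computes the pixel-to-centimetre scale from reference points with known
#' physical separations and assembles a calibrated [apparatus_geometry()].
#' The scale is the mean over all declared pairs of
#' (pixel distance / known cm separation).
#'
#' @param refs Data frame of annotated reference points with columns
#'   `point`, `x_px`, `y_px`.
#' @param pairs Data frame declaring known separations, columns
#'   `point1`, `point2`, `cm` (one row minimum, `cm > 0`).
#' @param layout Named list (or path to a flat key-value config file, see
#'   [read_layout_config()]) giving the arena layout. Length keys carry a
#'   `_px` or `_cm` suffix; `_px` values are converted using the calibrated
#'   scale. Recognised keys: `arena_w`, `arena_h`, `cage_a_x`, `cage_a_y`,
#'   `cage_b_x`, `cage_b_y`, `cage_radius`, and optionally
#'   `interaction_radius_cm`, `sniff_band_cm`, `rear_inset_cm`,
#'   `rear_fallback_cm`, `confidence_threshold`, `fps`.
#'
#' @return A calibrated `apparatus_geometry`.
#' @export
#' @examples
#' refs <- data.frame(point = c("p1", "p2"), x_px = c(0, 100), y_px = c(0, 0))
#' pairs <- data.frame(point1 = "p1", point2 = "p2", cm = 10)
#' layout <- list(arena_w_cm = 60, arena_h_cm = 40,
#'                cage_a_x_cm = 10, cage_a_y_cm = 20,
#'                cage_b_x_cm = 50, cage_b_y_cm = 20, cage_radius_cm = 5)
#' calibrate_geometry(refs, pairs, layout)$px_per_cm  # 10
calibrate_geometry <- function(refs, pairs, layout) {
  stopifnot(is.data.frame(refs),
            all(c("point", "x_px", "y_px") %in% names(refs)),
            is.data.frame(pairs),
            all(c("point1", "point2", "cm") %in% names(pairs)),
            nrow(pairs) >= 1, nrow(refs) >= 2)
  if (any(pairs$cm <= 0)) stop("known separations must be positive")
  if (is.character(layout)) layout <- read_layout_config(layout)

  scale_of_pair <- function(p1, p2, cm) {
    i <- match(p1, refs$point); j <- match(p2, refs$point)
    if (is.na(i) || is.na(j)) {
      stop("reference pair (", p1, ", ", p2, ") not found in refs")
    }
    d_px <- sqrt((refs$x_px[i] - refs$x_px[j])^2 +
                 (refs$y_px[i] - refs$y_px[j])^2)
    if (d_px == 0) {
      stop("zero pixel distance between distinct reference points ",
           p1, " and ", p2)
    }
    d_px / cm
  }
  px_per_cm <- mean(mapply(scale_of_pair, pairs$point1, pairs$point2,
                           pairs$cm))

  # resolve a length key that may be given in px or cm
  len <- function(key, default = NULL) {
    if (!is.null(layout[[paste0(key, "_cm")]])) {
      return(as.numeric(layout[[paste0(key, "_cm")]]))
    }
    if (!is.null(layout[[paste0(key, "_px")]])) {
      return(as.numeric(layout[[paste0(key, "_px")]]) / px_per_cm)
    }
    if (is.null(default)) stop("layout is missing required key: ", key)
    default
  }
  opt <- function(key, default) {
    if (!is.null(layout[[key]])) as.numeric(layout[[key]]) else default
  }

  cage_r <- len("cage_radius")
  apparatus_geometry(
    px_per_cm = px_per_cm,
    arena_w_cm = len("arena_w"), arena_h_cm = len("arena_h"),
    cage_a_center = c(len("cage_a_x"), len("cage_a_y")),
    cage_b_center = c(len("cage_b_x"), len("cage_b_y")),
    cage_radius_cm = cage_r,
    interaction_radius_cm = opt("interaction_radius_cm", 5),
    sniff_band_cm = opt("sniff_band_cm", 3),
    rear_inset_cm = opt("rear_inset_cm", 0),
    rear_fallback_cm = opt("rear_fallback_cm", cage_r + 2),
    confidence_threshold = opt("confidence_threshold", 0.6),
    fps = opt("fps", 25)
  )
}

#' Read or write a flat key-value configuration file
#'
#' Minimal YAML-style `key: value` text format used for layout and geometry
#' configs. Lines starting with `#` and blank lines are ignored; values are
#' numeric where possible.
#'
#' @param path File path.
#' @return `read_layout_config`: a named list.
#' @export
read_layout_config <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z0-9_.]+)\\s*:\\s*(.*)$", ln))[[1]]
    if (length(m) != 3) stop("cannot parse config line: ", ln)
    val <- m[3]
    num <- suppressWarnings(as.numeric(val))
    out[[m[2]]] <- if (is.na(num)) val else num
  }
  out
}

#' @rdname read_layout_config
#' @param geom An `apparatus_geometry` to serialize.
#' @return `write_geometry`: `path`, invisibly.
#' @export
write_geometry <- function(geom, path) {
  stopifnot(inherits(geom, "apparatus_geometry"))
  kv <- c(
    px_per_cm = geom$px_per_cm,
    arena_w_cm = geom$arena_w_cm, arena_h_cm = geom$arena_h_cm,
    cage_a_x_cm = geom$cage_a_center[1], cage_a_y_cm = geom$cage_a_center[2],
    cage_b_x_cm = geom$cage_b_center[1], cage_b_y_cm = geom$cage_b_center[2],
    cage_radius_cm = geom$cage_radius_cm,
    interaction_radius_cm = geom$interaction_radius_cm,
    sniff_band_cm = geom$sniff_band_cm,
    rear_inset_cm = geom$rear_inset_cm,
    rear_fallback_cm = geom$rear_fallback_cm,
    confidence_threshold = geom$confidence_threshold,
    fps = geom$fps
  )
  writeLines(sprintf("%s: %.17g", names(kv), kv), path)
  invisible(path)
}

#' @rdname read_layout_config
#' @return `read_geometry`: an `apparatus_geometry`.
#' @export
read_geometry <- function(path) {
  kv <- read_layout_config(path)
  apparatus_geometry(
    px_per_cm = kv$px_per_cm,
    arena_w_cm = kv$arena_w_cm, arena_h_cm = kv$arena_h_cm,
    cage_a_center = c(kv$cage_a_x_cm, kv$cage_a_y_cm),
    cage_b_center = c(kv$cage_b_x_cm, kv$cage_b_y_cm),
    cage_radius_cm = kv$cage_radius_cm,
    interaction_radius_cm = kv$interaction_radius_cm,
    sniff_band_cm = kv$sniff_band_cm,
    rear_inset_cm = kv$rear_inset_cm,
    rear_fallback_cm = kv$rear_fallback_cm,
    confidence_threshold = kv$confidence_threshold,
    fps = kv$fps
  )
}

#' @export
print.apparatus_geometry <- function(x, ...) {
  cat("Apparatus geometry (overhead view, cm)\n")
  cat(sprintf("  arena: %g x %g cm, %g px/cm, %g fps\n",
              x$arena_w_cm, x$arena_h_cm, x$px_per_cm, x$fps))
  cat(sprintf("  cage A (%g, %g), cage B (%g, %g), radius %g cm\n",
              x$cage_a_center[1], x$cage_a_center[2],
              x$cage_b_center[1], x$cage_b_center[2], x$cage_radius_cm))
  cat(sprintf("  interaction %g cm | sniff band %g cm | rear inset %g cm | fallback %g cm\n",
              x$interaction_radius_cm, x$sniff_band_cm, x$rear_inset_cm,
              x$rear_fallback_cm))
  cat(sprintf("  confidence gate >= %g\n", x$confidence_threshold))
  invisible(x)
}
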