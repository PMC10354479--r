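#' Wing posture specification
#'
#' A posture fixes the sweep angle of each leading-edge segment and the
#' hindlimb orientation used when a planform is assembled.  The coordinate
#' frame is x lateral (positive away from the midline), y longitudinal
#' (positive anterior); sweep angles are measured from the transverse (+x)
#' axis with posterior sweep positive.  The femur is oriented `femur_angle`
#' degrees postero-laterally from the acetabulum (45 by default) and the
#' tibia runs parallel to the body midline.
#'
#' @param angles Named numeric vector of sweep angles in degrees, one entry
#'   per leading-edge segment (`humerus`, `ulna_radius`, `mcIV`, `wp1` ...
#'   `wp4`, or `wp34` when WP3--4 are combined).  Angles must lie in
#'   (-90, 90).
#' @param femur_angle Femur angle in degrees, in (0, 90].
#' @param tibia_parallel Logical; the tibia is modelled parallel to the
#'   midline (the only supported option).
#' @param name Posture label.
#' @return An object of class `posture`.
#' @seealso [posture_preset()]
#' @export
posture <- function(angles, femur_angle = 45, tibia_parallel = TRUE,
                    name = "custom") {
  stopifnot(is.numeric(angles), !is.null(names(angles)))
  if (any(angles <= -90 | angles >= 90))
    stop("sweep angles must lie in (-90, 90) degrees")
  if (femur_angle <= 0 || femur_angle > 90)
    stop("femur_angle must lie in (0, 90] degrees")
  if (!isTRUE(tibia_parallel))
    stop("only tibia parallel to the midline is supported")
  structure(list(name = name, angles = angles, femur_angle = femur_angle,
                 tibia_parallel = TRUE),
            class = "posture")
}

#' @export
print.posture <- function(x, ...) {
  cat("Posture '", x$name, "': femur at ", x$femur_angle,
      " deg, tibia parallel to midline\n", sep = "")
  print(x$angles)
  invisible(x)
}

# Sweep-angle tables, degrees from the transverse axis, posterior positive.
# These are editable configuration, approximated from published wing
# reconstructions, not measured ground truth.  The anteriorly swept proximal
# wing of the pterodactyloid preset brings centre of mass and centre of
# pressure closer together; it is shared by Pteranodon, Sinopterus and
# Pterodactylus (the same posture choice the planform model makes for all
# three).  The neutral preset keeps the leading edge fundamentally
# perpendicular to the body's long axis.
.posture_tables <- list(
  neutral = c(humerus = 10, ulna_radius = 5, mcIV = 0,
              wp1 = 5, wp2 = 15, wp3 = 30, wp4 = 50),
  pterodactyloid = c(humerus = 25, ulna_radius = -15, mcIV = -5,
                     wp1 = 10, wp2 = 25, wp3 = 40, wp4 = 60),
  rhamphorhynchid = c(humerus = 30, ulna_radius = -5, mcIV = 5,
                      wp1 = 10, wp2 = 20, wp3 = 35, wp4 = 55),
  anurognathid = c(humerus = 30, ulna_radius = 0, mcIV = 5,
                   wp1 = 10, wp2 = 20, wp34 = 45))

#' Posture presets
#'
#' Taxon-specific presets (`"Pteranodon"`, `"Sinopterus"`, `"Pterodactylus"`
#' share one pterodactyloid posture; `"Rhamphorhynchus"` and
#' `"anurognathids"` have their own) and a `"neutral"` posture with the
#' leading edge fundamentally perpendicular to the long axis of the body.
#' Preset angles are editable configuration approximated from published
#' reconstructions; see [posture()] for conventions.
#'
#' @param name Preset name: one of the five taxa or `"neutral"`.
#' @param combine_wp34 Use a single combined `wp34` segment (automatic for
#'   the anurognathid preset).  The combined angle is the mean of the wp3 and
#'   wp4 angles (the average posture of the two bones).
#' @return A [posture()].
#' @export
#' @examples
#' posture_preset("Pteranodon")
#' posture_preset("neutral", combine_wp34 = TRUE)
posture_preset <- function(name, combine_wp34 = FALSE) {
  key <- switch(name,
                neutral = "neutral",
                Pteranodon = , Sinopterus = , Pterodactylus = "pterodactyloid",
                Rhamphorhynchus = "rhamphorhynchid",
                anurognathids = , anurognathid = "anurognathid",
                stop("no posture preset for '", name, "'"))
  ang <- .posture_tables[[key]]
  if ((combine_wp34 || key == "anurognathid") && !"wp34" %in% names(ang)) {
    wp34 <- mean(ang[c("wp3", "wp4")])
    ang <- c(ang[setdiff(names(ang), c("wp3", "wp4"))], wp34 = wp34)
  }
  posture(ang, name = if (key == "neutral") "neutral"
                      else paste0("taxon_specific:", name))
}

#' Read or write a posture as YAML
#'
#' Postures are plain configuration; these helpers serialise them so users
#' can edit joint angles outside R.
#'
#' @param x A [posture()].
#' @param file Path to a YAML file.
#' @return `write_posture_yaml()` returns `file` invisibly;
#'   `read_posture_yaml()` returns a [posture()].
#' @export
write_posture_yaml <- function(x, file) {
  stopifnot(inherits(x, "posture"))
  yaml::write_yaml(list(name = x$name, angles = as.list(x$angles),
                        femur_angle = x$femur_angle,
                        tibia_parallel = x$tibia_parallel), file)
  invisible(file)
}

#' @rdname write_posture_yaml
#' @export
read_posture_yaml <- function(file) {
  y <- yaml::read_yaml(file)
  posture(unlist(y$angles), femur_angle = y$femur_angle,
          tibia_parallel = y$tibia_parallel, name = y$name)
}
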