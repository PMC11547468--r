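# Rigid-rod (Clegg-model) DNA ruler: base pairs -> donor-to-surface
# separation, with tilt projection and first-order error propagation.

#' Describe a double-stranded DNA spacer construct
#'
#' @param bp Number of base pairs (>= 0).
#' @param rise_A Helical rise per base pair in Angstrom (default 3.4,
#'   B-form DNA).
#' @param offset_A Linker offset in Angstrom covering the spacers and
#'   binding terminals at both ends (default 27; with the defaults a
#'   20/40/60/80 bp duplex gives 95/163/231/299 A).
#' @param tilt_deg Tilt of the construct away from the surface normal,
#'   degrees in `[0, 90)`.
#' @param tilt_error_deg One-sigma uncertainty of the tilt, degrees.
#' @param project What the cosine projection applies to when tilted:
#'   `"duplex"` (default; the flexible linker's contribution is lumped in
#'   the offset and not projected) or `"full"` (project duplex plus
#'   offset, the convention of the case-table schema).
#' @return An object of class `dna_construct`.
#' @export
dna_construct <- function(bp, rise_A = 3.4, offset_A = 27, tilt_deg = 0,
                          tilt_error_deg = 0,
                          project = c("duplex", "full")) {
  project <- match.arg(project)
  if (any(bp < 0)) stop("base pairs must be >= 0")
  if (any(tilt_deg < 0 | tilt_deg >= 90)) stop("tilt must be in [0, 90)")
  if (any(tilt_error_deg < 0)) stop("tilt error must be >= 0")
  structure(list(bp = bp, rise_A = rise_A, offset_A = offset_A,
                 tilt_deg = tilt_deg, tilt_error_deg = tilt_error_deg,
                 project = project),
            class = "dna_construct")
}

#' Donor-to-surface separation of a DNA construct
#'
#' Rigid-rod length `rise * bp + offset`, with the tilted segment
#' projected by `cos(tilt)`.
#'
#' @param construct A [dna_construct()].
#' @return Separation in Angstrom.
#' @examples
#' clegg_distance(dna_construct(20))  # 95 A
#' clegg_distance(dna_construct(80))  # 299 A
#' @export
clegg_distance <- function(construct) {
  th <- construct$tilt_deg * pi / 180
  duplex <- construct$rise_A * construct$bp
  if (construct$project == "duplex")
    duplex * cos(th) + construct$offset_A
  else
    (duplex + construct$offset_A) * cos(th)
}

#' First-order separation error from tilt uncertainty
#'
#' Propagates the tilt one-sigma through the cosine projection:
#' `|d(separation)/d(theta)| * sigma_theta = L_projected_segment *
#' sin(theta) * sigma_theta(rad)`. Zero at zero tilt error and, to first
#' order, symmetric in the sign of the tilt perturbation.
#'
#' @param construct A [dna_construct()].
#' @return Error in Angstrom.
#' @export
distance_error <- function(construct) {
  th <- construct$tilt_deg * pi / 180
  seg <- construct$rise_A * construct$bp +
    if (construct$project == "full") construct$offset_A else 0
  seg * sin(th) * construct$tilt_error_deg * pi / 180
}
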