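#' Default measurement parameters
#'
#' All numeric defaults of the measurement pipeline live in this one record so
#' that the library functions, the command line interface and the test-suite
#' cannot drift apart.  The values mirror the published processing protocol:
#' outliers are points whose mean distance to their `k = 20` nearest
#' neighbours exceeds 0.30 m; the tree location circle is fitted to the lowest
#' 0.30 m slice; DBH to the 1.27--1.33 m slice above the tree base; the crown
#' starts at the first 0.10 m slice whose fitted radius jumps by at least 20%;
#' crown radii are measured every 5 degrees in a 0.10 m wide vertical slab,
#' and additionally in 2 m height bands up to 30 m.
#'
#' @return Named list of defaults:
#' \describe{
#'   \item{knn}{neighbour count for outlier removal (20)}
#'   \item{outlier_threshold}{mean k-NN distance cut-off, m (0.30)}
#'   \item{location_slice}{height of the basal location slice, m (0.30)}
#'   \item{dbh_slice_lo, dbh_slice_hi}{DBH slice bounds above tree base, m
#'     (1.27, 1.33)}
#'   \item{crown_jump}{relative radius jump marking the crown start (1.2)}
#'   \item{slice_height}{height of the crown-scan slices, m (0.10)}
#'   \item{crown_scan_max_frac}{crown-start scan cap as a fraction of tree
#'     height (0.60)}
#'   \item{min_circle_points}{minimum points for any slice circle fit (10)}
#'   \item{slab_width}{total width of the directional slab, m (0.10)}
#'   \item{angle_step}{azimuthal step of the crown radii, degrees (5)}
#'   \item{band_height}{height of the crown-radius bands, m (2)}
#'   \item{band_max_height}{upper end of the banded scan above base, m (30)}
#'   \item{unfitted_threshold}{point-to-cylinder distance above which a point
#'     counts as not fitted by the QSM, m (0.05)}
#' }
#' @examples
#' cm_defaults()$outlier_threshold
#' @export
cm_defaults <- function() {
  list(
    knn = 20L,
    outlier_threshold = 0.30,
    location_slice = 0.30,
    dbh_slice_lo = 1.27,
    dbh_slice_hi = 1.33,
    crown_jump = 1.2,
    slice_height = 0.10,
    crown_scan_max_frac = 0.60,
    min_circle_points = 10L,
    slab_width = 0.10,
    angle_step = 5,
    band_height = 2,
    band_max_height = 30,
    unfitted_threshold = 0.05
  )
}
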