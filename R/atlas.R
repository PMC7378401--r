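#' Desikan-Killiany cortical parcellation table
#'
#' Returns the fixed 68-region Desikan-Killiany (DK) atlas used to label
#' source-level ROI time courses: 34 regions per hemisphere, each with a
#' full name, a compact abbreviation (leading `l`/`r` plus an uppercase
#' stem, e.g. `rTP` for the right temporal pole), and a lobe assignment
#' used for lobe-level summaries of selected networks.
#'
#' ROI indices are 0-based and match the ROI axis of simulated and
#' imported epoch arrays: indices 0-33 are left-hemisphere regions,
#' 34-67 right-hemisphere, alphabetical within hemisphere.
#'
#' @return A data frame of class `roi_atlas` with columns `roi_index`
#'   (integer, 0..67), `name`, `abbrev`, `hemisphere` (`"L"`/`"R"`) and
#'   `lobe` (temporal/frontal/parietal/occipital/cingulate/insula).
#' @examples
#' atlas <- make_atlas()
#' nrow(atlas)                      # 68
#' table(atlas$hemisphere)          # 34 L, 34 R
#' atlas[atlas$abbrev == "rTP", ]   # Temporal pole R
#' @export
make_atlas <- function() {
  path <- system.file("extdata", "dk_atlas.csv", package = "erpdecode",
                      mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  tab$roi_index <- as.integer(tab$roi_index)
  stopifnot(nrow(tab) == 68L,
            identical(tab$roi_index, 0:67),
            !anyDuplicated(tab$abbrev),
            sum(tab$hemisphere == "L") == 34L,
            sum(tab$hemisphere == "R") == 34L)
  class(tab) <- c("roi_atlas", "data.frame")
  tab
}

#' ROI index sets by hemisphere
#'
#' Returns the 0-based ROI indices belonging to one hemisphere (or both),
#' used to restrict decoding to left- or right-hemisphere feature sets.
#'
#' @param atlas An atlas table from [make_atlas()].
#' @param side `"L"`, `"R"` or `"both"`.
#' @return Integer vector of 0-based ROI indices.
#' @examples
#' atlas <- make_atlas()
#' length(hemisphere_mask(atlas, "L"))     # 34
#' length(hemisphere_mask(atlas, "both"))  # 68
#' @export
hemisphere_mask <- function(atlas, side = c("both", "L", "R")) {
  side <- match.arg(side)
  if (side == "both") return(atlas$roi_index)
  atlas$roi_index[atlas$hemisphere == side]
}

#' @export
print.roi_atlas <- function(x, ...) {
  cat("Desikan-Killiany parcellation:", nrow(x), "ROIs (",
      sum(x$hemisphere == "L"), "L /", sum(x$hemisphere == "R"), "R )\n")
  print.data.frame(utils::head(as.data.frame(x), 6), row.names = FALSE)
  cat("...", nrow(x) - 6, "more rows\n")
  invisible(x)
}

# Abbreviations of the 12 regions reported as the stable clear-speech
# network; the simulator plants its default group effect there so that
# recovery tests are interpretable against a known target set.
clear_network_abbrevs <- function() {
  c("rTP", "rFUS", "lSP", "rPRC", "lPRC", "rCMF",
    "lPREC", "lMT", "rIST", "lBKS", "rBKS", "lST")
}

#' Default discriminative ROI set
#'
#' The 12-region network used as the simulator's default location for the
#' planted group effect (bilateral superior temporal bank, temporal pole R,
#' fusiform R, precentral gyri, and associated parietal/frontal regions).
#'
#' @param atlas An atlas table from [make_atlas()].
#' @return Integer vector of 0-based ROI indices (length 12).
#' @export
default_discriminative_rois <- function(atlas = make_atlas()) {
  sort(atlas$roi_index[match(clear_network_abbrevs(), atlas$abbrev)])
}
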