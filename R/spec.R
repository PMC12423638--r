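# User prior knowledge of the resection site: hemisphere and lobe initials.

LOBE_INITIALS <- c(T = "Temporal", F = "Frontal", O = "Occipital", P = "Parietal")

#' Resection specification
#'
#' Encodes the user's prior knowledge of the resection site. The temporal
#' filter also includes the subcortical and insular regions (a temporal-lobe
#' resection routinely involves mesial structures). Defaults search both
#' hemispheres and all lobes.
#'
#' @param hemisphere `"L"`, `"R"` or `"both"` (default).
#' @param lobes Character vector of lobe initials from `T, F, O, P`, or
#'   `"all"` (default).
#' @return An object of class `resection_spec`.
#' @export
resection_spec <- function(hemisphere = "both", lobes = "all") {
  hemisphere <- toupper(as.character(hemisphere))
  if (identical(hemisphere, "BOTH")) hemisphere <- "both"
  if (!hemisphere %in% c("L", "R", "both"))
    stop("hemisphere must be one of L, R, both")
  lobes <- toupper(as.character(lobes))
  lobes <- lobes[nzchar(lobes)]
  if (!length(lobes) || identical(lobes, "ALL")) {
    lobe_names <- c("Frontal", "Parietal", "Temporal", "Occipital",
                    "Insula", "SubCortical")
    initials <- "all"
  } else {
    bad <- setdiff(lobes, names(LOBE_INITIALS))
    if (length(bad))
      stop("unknown lobe initial(s): ", paste(bad, collapse = ", "),
           " (valid: T, F, O, P, or 'all')")
    lobe_names <- unique(unlist(lapply(lobes, function(l) {
      if (l == "T") c("Temporal", "SubCortical", "Insula") else LOBE_INITIALS[[l]]
    })))
    initials <- lobes
  }
  structure(list(hemisphere = hemisphere, lobes = initials,
                 lobe_names = lobe_names),
            class = "resection_spec")
}

#' @export
print.resection_spec <- function(x, ...) {
  cat(sprintf("<resection_spec> hemisphere: %s; lobes: %s (%s)\n",
              x$hemisphere, paste(x$lobes, collapse = ","),
              paste(x$lobe_names, collapse = ", ")))
  invisible(x)
}

# TRUE when the spec is the uninformative default (search everywhere).
spec_is_default <- function(spec) {
  identical(spec$hemisphere, "both") && identical(spec$lobes, "all")
}

# Atlas codes selected by a spec.
resection_spec_codes <- function(spec) {
  hemis <- switch(spec$hemisphere, L = "L", R = "R", both = c("L", "R"))
  codes <- integer(0)
  for (h in hemis)
    codes <- c(codes, LOBE_CODE[spec$lobe_names] + HEMI_OFFSET[[h]])
  as.integer(codes)
}

#' Parse hemisphere and lobe initials into a resection specification
#'
#' Case-insensitive; lobes may be comma-, space- or semicolon-separated (e.g.
#' `"T,F"`). Empty strings give the defaults (both hemispheres, all lobes).
#'
#' @param hemisphere String: `"L"`, `"R"`, `"both"` or `""`.
#' @param lobes String of initials, or `""`/`"all"`.
#' @return A [resection_spec()].
#' @export
parse_resection_spec <- function(hemisphere = "", lobes = "") {
  h <- trimws(hemisphere)
  if (!nzchar(h)) h <- "both"
  l <- trimws(unlist(strsplit(lobes, "[,; ]+")))
  l <- l[nzchar(l)]
  if (!length(l)) l <- "all"
  resection_spec(h, l)
}
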