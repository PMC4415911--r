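#' Microsatellite marker panels
#'
#' The marker sets used for instability calling: the five consensus NCI
#' markers (mononucleotide BAT25/BAT26 and dinucleotide D2S123, D5S346,
#' D17S250), two additional dinucleotide markers (D18S64, D18S69), and the
#' seven EMAST tetranucleotide markers (MYCL1, D20S82, D20S85, L17835,
#' D8S321, D9S242, D19S394).
#'
#' @return Named list of character vectors: `nci_mono`, `nci_di`,
#'   `extra_di`, `emast`.
#' @export
marker_panel <- function() {
  list(
    nci_mono = c("BAT25", "BAT26"),
    nci_di = c("D2S123", "D5S346", "D17S250"),
    extra_di = c("D18S64", "D18S69"),
    emast = c("MYCL1", "D20S82", "D20S85", "L17835", "D8S321", "D9S242",
              "D19S394")
  )
}

#' Classify MSI and EMAST status from marker stability calls
#'
#' For each of two panels - the five NCI markers alone, and the NCI markers
#' extended with the two additional dinucleotide markers - the status is:
#' `MSS` with zero unstable markers; `MSI_L` with at least one unstable
#' marker but an unstable fraction below `low_fraction`; `MSI_H` otherwise.
#' EMAST positivity is instability at one or more of the seven EMAST
#' markers. Failed marker assays (`"f"`) are dropped from both numerator and
#' denominator.
#'
#' @param calls Named character vector (or single-row `data.frame`) of
#'   per-marker calls: `"+"` unstable, `"-"` stable, `"f"` failed. Must
#'   cover the seven NCI + dinucleotide markers (minus failures).
#' @param low_fraction MSI-L/MSI-H boundary on the unstable fraction
#'   (default 0.30).
#' @return List: `nci_status`, `nci_plus_d_status`, `emast_positive`,
#'   `unstable_fraction_nci`, `unstable_fraction_nci_d`.
#' @examples
#' calls <- setNames(rep("-", 14), unlist(marker_panel()))
#' calls[c("D18S69", "D18S64")] <- "+"
#' classify_msi(calls)  # MSS on NCI, MSI_L on NCI+D
#' @export
classify_msi <- function(calls, low_fraction = 0.30) {
  if (is.data.frame(calls)) {
    stopifnot(nrow(calls) == 1)
    calls <- unlist(calls[1, , drop = TRUE])
  }
  panel <- marker_panel()
  status_of <- function(markers) {
    x <- calls[intersect(markers, names(calls))]
    x <- x[!is.na(x) & x != "f"]
    if (!length(x)) stop("no informative markers left in panel", call. = FALSE)
    frac <- mean(x == "+")
    n_unstable <- sum(x == "+")
    status <- if (n_unstable == 0) "MSS"
      else if (frac < low_fraction) "MSI_L"
      else "MSI_H"
    list(status = status, frac = frac)
  }
  nci <- status_of(c(panel$nci_mono, panel$nci_di))
  ncid <- status_of(c(panel$nci_mono, panel$nci_di, panel$extra_di))
  em <- calls[intersect(panel$emast, names(calls))]
  em <- em[!is.na(em) & em != "f"]
  list(nci_status = nci$status,
       nci_plus_d_status = ncid$status,
       emast_positive = any(em == "+"),
       unstable_fraction_nci = nci$frac,
       unstable_fraction_nci_d = ncid$frac)
}

#' Classify every sample of a marker-call table
#'
#' @param markers A `data.frame` from [read_marker_table()].
#' @param low_fraction Passed to [classify_msi()].
#' @return `markers` with added columns `NCI_status`, `NCI_D_status`,
#'   `EMAST_positive`, `frac_unstable_NCI`, `frac_unstable_NCI_D` and, when
#'   `IHC_Normal`/`IHC_Tumor` columns are present, `IHC_change` from
#'   [score_ihc()].
#' @export
classify_msi_table <- function(markers, low_fraction = 0.30) {
  mk <- intersect(unlist(marker_panel()), names(markers))
  res <- lapply(seq_len(nrow(markers)), function(i) {
    classify_msi(unlist(markers[i, mk, drop = TRUE]), low_fraction)
  })
  markers$NCI_status <- vapply(res, `[[`, character(1), "nci_status")
  markers$NCI_D_status <- vapply(res, `[[`, character(1), "nci_plus_d_status")
  markers$EMAST_positive <- vapply(res, `[[`, logical(1), "emast_positive")
  markers$frac_unstable_NCI <-
    vapply(res, `[[`, numeric(1), "unstable_fraction_nci")
  markers$frac_unstable_NCI_D <-
    vapply(res, `[[`, numeric(1), "unstable_fraction_nci_d")
  if (all(c("IHC_Normal", "IHC_Tumor") %in% names(markers))) {
    nrm <- parse_ihc(markers$IHC_Normal)
    tmr <- parse_ihc(markers$IHC_Tumor)
    markers$IHC_change <- mapply(function(a, b) score_ihc(a, b)$change,
                                 nrm, tmr)
  }
  markers
}

# "3+" -> 3, "0" -> 0
parse_ihc <- function(x) as.integer(sub("\\+$", "", x))

#' Score immunohistochemistry staining change
#'
#' Semi-quantitative staining scores: 0 no staining, 1 weak, 2 intermediate,
#' 3 strong. The change from normal to tumor tissue is `marked_loss` when
#' the score drops by at least `loss_delta` (default 2), `reduced` for a
#' one-point drop, `stable` for no change, `increased` otherwise.
#'
#' @param normal,tumor Integer scores in 0..3.
#' @param loss_delta Minimum drop called a marked loss (default 2).
#' @return List: `normal_score`, `tumor_score`, `change`.
#' @examples
#' score_ihc(2, 0)  # marked_loss
#' score_ihc(3, 2)  # reduced
#' @export
score_ihc <- function(normal, tumor, loss_delta = 2) {
  if (!normal %in% 0:3 || !tumor %in% 0:3) {
    stop("IHC scores must be integers in 0..3", call. = FALSE)
  }
  d <- normal - tumor
  change <- if (d >= loss_delta) "marked_loss"
    else if (d >= 1) "reduced"
    else if (d == 0) "stable"
    else "increased"
  list(normal_score = normal, tumor_score = tumor, change = change)
}
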