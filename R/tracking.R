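#' Define a mixture-spiking scheme
#'
#' Peak tracking across design runs relies on injecting several partial
#' mixtures of the analytes at every design condition: which mixtures a peak
#' shows up in (its membership signature) narrows down its identity, and
#' relative areas against the nominal spiked concentrations settle the rest.
#'
#' @param composition A data frame with columns `mixture_id`, `analyte`,
#'   `conc_ug_ml`. The union of mixtures must cover every analyte and at
#'   least one mixture must contain all of them (the full mixture anchors
#'   the peak roster).
#' @return An object of class `mixture_scheme`.
#' @export
mixture_scheme <- function(composition) {
  stopifnot(is.data.frame(composition))
  need <- c("mixture_id", "analyte", "conc_ug_ml")
  if (!all(need %in% names(composition))) {
    stop("composition needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (any(composition$conc_ug_ml <= 0)) {
    stop("concentrations must be positive", call. = FALSE)
  }
  analytes <- unique(composition$analyte)
  by_mix <- split(composition$analyte, composition$mixture_id)
  if (!any(vapply(by_mix, function(m) all(analytes %in% m), logical(1)))) {
    stop("at least one mixture must contain every analyte", call. = FALSE)
  }
  structure(list(composition = tibble::as_tibble(composition),
                 mixtures = names(by_mix), analytes = analytes),
            class = "mixture_scheme")
}

#' The three-mixture ezetimibe tracking scheme
#'
#' The spiking scheme used for the ezetimibe impurity-profiling study:
#' mix1 holds the API and all eight related substances, mix2 six of the
#' impurities, mix3 the remaining two (desfluoro ezetimibe and the THP
#' compound), at the nominal concentrations of the study.
#'
#' @return A [mixture_scheme()].
#' @export
ezetimibe_scheme <- function() {
  mix1 <- tibble::tribble(
    ~analyte, ~conc_ug_ml,
    "ezetimibe", 1000,
    "ezetimibe diol", 12,
    "desfluoro ezetimibe", 4,
    "monofluoro ezetimibe", 6,
    "RRS ezetimibe", 8,
    "THP compound", 6,
    "ezetimibe ketone", 8,
    "benzylated ezetimibe", 8,
    "TBDMS ketone", 6
  )
  mix2 <- dplyr::filter(mix1, .data$analyte %in% c(
    "ezetimibe diol", "monofluoro ezetimibe", "RRS ezetimibe",
    "ezetimibe ketone", "benzylated ezetimibe", "TBDMS ketone"))
  mix3 <- dplyr::filter(mix1, .data$analyte %in% c(
    "desfluoro ezetimibe", "THP compound"))
  mixture_scheme(dplyr::bind_rows(
    dplyr::mutate(mix1, mixture_id = "mix1"),
    dplyr::mutate(mix2, mixture_id = "mix2"),
    dplyr::mutate(mix3, mixture_id = "mix3")))
}

#' Membership signature of an analyte
#'
#' @param analyte_id Analyte name.
#' @param scheme A [mixture_scheme()].
#' @return Named logical vector over the scheme's mixtures: in which
#'   mixtures the analyte is present.
#' @export
membership_signature <- function(analyte_id, scheme) {
  stopifnot(inherits(scheme, "mixture_scheme"))
  if (!analyte_id %in% scheme$analytes) {
    stop("unknown analyte: ", analyte_id, call. = FALSE)
  }
  comp <- scheme$composition
  vapply(scheme$mixtures, function(m) {
    analyte_id %in% comp$analyte[comp$mixture_id == m]
  }, logical(1))
}

# Signature of an observed full-mixture peak: which mixtures contain a peak
# within rt_tol of it.
observed_signature <- function(rt, peaks_by_mix, mixtures, rt_tol) {
  vapply(mixtures, function(m) {
    p <- peaks_by_mix[[m]]
    !is.null(p) && any(abs(p$rt_min - rt) <= rt_tol)
  }, logical(1))
}

#' Assign analyte identities to peaks of one design condition
#'
#' Labels the peaks of the full-mixture injection of one condition using,
#' in order: (1) the presence/absence signature across the partial-mixture
#' injections (peaks matched between injections within `rt_tol` minutes);
#' (2) within groups sharing a signature, correspondence between observed
#' areas and the nominal spiked concentrations (rank matching after
#' within-group normalization); (3) within-group elution order when areas
#' are indistinguishable. Peaks whose area evidence is ambiguous — two
#' candidates with areas within 10% and identical concentrations — are
#' flagged, never silently guessed.
#'
#' @param peaks A data frame of the observed peaks of one condition:
#'   columns `mixture_id`, `rt_min`, `area` (all mixtures of the scheme).
#' @param scheme A [mixture_scheme()].
#' @param rt_tol Retention-time matching window between injections of the
#'   same condition (min), default 0.1.
#' @return A tibble with one row per full-mixture peak: `rt_min`, `area`,
#'   `analyte` (NA when ambiguous), `ambiguous`, `signature`.
#' @export
assign_peaks <- function(peaks, scheme, rt_tol = 0.1) {
  stopifnot(inherits(scheme, "mixture_scheme"), is.data.frame(peaks))
  need <- c("mixture_id", "rt_min", "area")
  if (!all(need %in% names(peaks))) {
    stop("peaks needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  full_mix <- scheme$mixtures[vapply(scheme$mixtures, function(m) {
    all(scheme$analytes %in%
          scheme$composition$analyte[scheme$composition$mixture_id == m])
  }, logical(1))][1]
  missing_mix <- setdiff(scheme$mixtures, unique(peaks$mixture_id))
  if (length(missing_mix)) {
    stop("incomplete evidence: no injection for mixture(s) ",
         paste(missing_mix, collapse = ", "), call. = FALSE)
  }
  peaks_by_mix <- split(tibble::as_tibble(peaks), peaks$mixture_id)
  anchor <- dplyr::arrange(peaks_by_mix[[full_mix]], .data$rt_min)

  sig_string <- function(sig) paste(ifelse(sig, "1", "0"), collapse = "")
  analyte_sigs <- vapply(scheme$analytes, function(a) {
    sig_string(membership_signature(a, scheme))
  }, character(1))

  anchor$signature <- vapply(anchor$rt_min, function(rt) {
    sig_string(observed_signature(rt, peaks_by_mix, scheme$mixtures, rt_tol))
  }, character(1))
  anchor$analyte <- NA_character_
  anchor$ambiguous <- FALSE

  conc_of <- function(a) {
    comp <- scheme$composition
    comp$conc_ug_ml[comp$analyte == a & comp$mixture_id == full_mix][1]
  }

  for (sig in unique(anchor$signature)) {
    idx <- which(anchor$signature == sig)
    cands <- names(analyte_sigs)[analyte_sigs == sig]
    if (length(cands) == 0L) {
      anchor$ambiguous[idx] <- TRUE
      next
    }
    if (length(cands) == 1L && length(idx) == 1L) {
      anchor$analyte[idx] <- cands
      next
    }
    if (length(cands) < length(idx)) {
      # more peaks than candidates: evidence is inconsistent, flag them all
      anchor$ambiguous[idx] <- TRUE
      next
    }
    if (length(cands) > length(idx)) {
      # fewer peaks than candidates (some member was lost to a collision
      # elsewhere): keep the candidate subset whose spiked amounts best
      # explain the observed areas in absolute terms, then fall through to
      # the usual within-group matching
      concs_all <- vapply(cands, conc_of, numeric(1))
      subsets <- utils::combn(length(cands), length(idx), simplify = FALSE)
      cost <- vapply(subsets, function(sel) {
        sum(abs(log(sort(anchor$area[idx])) - log(sort(concs_all[sel]))))
      }, numeric(1))
      best <- subsets[[which.min(cost)]]
      # only trust the subset when each area sits within the plausible
      # response band of its matched concentration
      ratios <- sort(anchor$area[idx]) / sort(concs_all[best])
      if (any(ratios < 1 / 1.6 | ratios > 1.6)) {
        anchor$ambiguous[idx] <- TRUE
        next
      }
      cands <- cands[best]
    }
    # area correspondence: rank-match normalized areas to normalized
    # concentrations (tolerant to a shared response scale within the group)
    concs <- vapply(cands, conc_of, numeric(1))
    areas <- anchor$area[idx]
    ord_peaks <- order(areas)
    ord_cands <- order(concs)
    assigned <- character(length(idx))
    assigned[ord_peaks] <- cands[ord_cands]
    # ambiguity: two peaks with areas within 10% competing for candidates
    # with identical concentrations cannot be told apart by area; elution
    # order only helps when the candidates' order is itself implied by a
    # resolved neighbour, which single-condition evidence cannot supply
    amb <- rep(FALSE, length(idx))
    sa <- sort(areas)
    sc <- sort(concs)
    for (i in seq_len(length(idx) - 1L)) {
      close_area <- sa[i + 1] / sa[i] <= 1.1
      same_conc <- sc[i] == sc[i + 1]
      if (close_area && same_conc) {
        amb[ord_peaks[c(i, i + 1)]] <- TRUE
      }
    }
    anchor$analyte[idx] <- ifelse(amb, NA_character_, assigned)
    anchor$ambiguous[idx] <- amb
  }
  # partial injection: a label may appear at most once
  dup <- anchor$analyte[!is.na(anchor$analyte)]
  if (anyDuplicated(dup)) {
    bad <- unique(dup[duplicated(dup)])
    anchor$ambiguous[anchor$analyte %in% bad] <- TRUE
    anchor$analyte[anchor$analyte %in% bad] <- NA_character_
  }
  dplyr::select(anchor, "rt_min", "area", "analyte", "ambiguous", "signature")
}

#' Label corner-run peak lists into a calibration table
#'
#' Runs [assign_peaks()] for every design condition of a multi-run peak
#' list and emits a corner-run table ready for [assemble_cube()].
#'
#' @param peaklists A data frame with columns `run_id`, `mixture_id`,
#'   `rt_min`, `area` covering all runs of a design.
#' @param design A [build_design()] table supplying the run conditions.
#' @param scheme A [mixture_scheme()].
#' @param rt_tol Matching window in minutes.
#' @return A corner-run tibble (`run_id`, `tG_min`, `temp_c`,
#'   `ternary_fraction`, `flow_ml_min`, `analyte`, `rt_min`, `area`) with
#'   ambiguous peaks omitted (they carry no label).
#' @export
track_peaks <- function(peaklists, design, scheme, rt_tol = 0.1) {
  stopifnot(is.data.frame(peaklists), is.data.frame(design))
  purrr::map_dfr(design$run_id, function(rid) {
    sub <- dplyr::filter(peaklists, .data$run_id == rid)
    lab <- assign_peaks(sub, scheme, rt_tol = rt_tol)
    lab <- dplyr::filter(lab, !is.na(.data$analyte))
    drow <- design[design$run_id == rid, ]
    tibble::tibble(run_id = rid, tG_min = drow$tG_min,
                   temp_c = drow$temp_c,
                   ternary_fraction = drow$ternary_fraction,
                   flow_ml_min = drow$flow_ml_min,
                   analyte = lab$analyte, rt_min = lab$rt_min,
                   area = lab$area)
  })
}
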