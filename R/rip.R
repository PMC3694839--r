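# Computational side of the anti-m5C pulldown validation: per-base coverage
# profiles, median-based cross-library normalisation, fold enrichment at
# candidate sites, and simple peak flagging.

#' Per-base coverage profile over a feature
#'
#' @param aln alignment/placement table with rname, pos, end.
#' @param feature one-row data.frame/list with seqid, start, end (and
#'   optionally feature_id).
#' @param label library label (e.g. "IP", "control-IP", "input").
#' @return list of class \code{CoverageProfile}: rname, start, end, cov
#'   (length = feature length), label.
#' @export
coverage_profile <- function(aln, feature, label = "IP") {
  aln <- data.table::as.data.table(aln)
  flen <- feature$end - feature$start + 1L
  delta <- integer(flen + 1L)
  sub <- aln[rname == feature$seqid & pos <= feature$end & end >= feature$start]
  if (nrow(sub)) {
    s <- pmax(sub$pos, feature$start) - feature$start + 1L
    e <- pmin(sub$end, feature$end) - feature$start + 1L
    for (i in seq_along(s)) {
      delta[s[i]] <- delta[s[i]] + 1L
      delta[e[i] + 1L] <- delta[e[i] + 1L] - 1L
    }
  }
  structure(list(rname = feature$seqid, start = feature$start,
                 end = feature$end, cov = cumsum(delta[seq_len(flen)]),
                 label = label),
            class = "CoverageProfile")
}

#' Median-normalised fold enrichment across libraries
#'
#' Every library is rescaled so that its median coverage over the feature
#' equals the IP library's median (the IP median is the reference point);
#' per-base fold enrichment is then coverage divided by the IP median. The
#' normalisation is scale-invariant: multiplying any library's coverage by a
#' positive constant leaves its enrichment profile unchanged. A zero median
#' falls back to the mean with a warning.
#'
#' @param ip \code{CoverageProfile} of the IP library.
#' @param others list of \code{CoverageProfile}s over the same feature.
#' @return list of profiles (IP first), each with an \code{enrich} vector
#'   added.
#' @export
normalize_and_enrich <- function(ip, others = list()) {
  centre <- function(p) {
    m <- stats::median(p$cov)
    if (m == 0) {
      warning("zero median coverage in library '", p$label,
              "'; falling back to the mean")
      m <- mean(p$cov)
    }
    m
  }
  m_ip <- centre(ip)
  if (m_ip == 0) stop("IP library has no coverage over the feature")
  ip$enrich <- ip$cov / m_ip
  out <- list(ip)
  for (p in others) {
    if (p$start != ip$start || p$end != ip$end || p$rname != ip$rname)
      stop("all profiles must cover the same feature")
    m <- centre(p)
    scaled <- if (m == 0) p$cov else p$cov * (m_ip / m)
    p$enrich <- scaled / m_ip
    out[[length(out) + 1L]] <- p
  }
  names(out) <- vapply(out, `[[`, character(1), "label")
  out
}

#' Flag candidate sites supported by IP enrichment
#'
#' A candidate site is "supported" when the maximum fold enrichment within
#' half a window of it exceeds \code{min_fold} in the IP library but in none
#' of the control libraries. Sites with no IP coverage in the window are
#' flagged low-coverage.
#'
#' @param profiles named list from \code{\link{normalize_and_enrich}} (IP
#'   first); controls are every non-first profile.
#' @param sites data.frame with rname, pos of candidate sites.
#' @param window full window width in nt (default 100; the search spans
#'   +/- window/2 around each site).
#' @param min_fold fold-enrichment cutoff (default 5).
#' @return data.table per site: ip_max, control_max, supported, low_coverage.
#' @export
flag_sites <- function(profiles, sites, window = 100L, min_fold = 5) {
  ip <- profiles[[1]]
  ctrl <- profiles[-1]
  sites <- data.table::as.data.table(sites)
  half <- window %/% 2L
  win_max <- function(p, r, pos) {
    if (p$rname != r) return(NA_real_)
    lo <- max(p$start, pos - half)
    hi <- min(p$end, pos + half)
    if (lo > hi) return(NA_real_)
    max(p$enrich[(lo:hi) - p$start + 1L])
  }
  out <- sites[, .(rname, pos)]
  out[, ip_max := mapply(function(r, x) win_max(ip, r, x), rname, pos)]
  out[, control_max := if (length(ctrl) == 0L) NA_real_ else
    mapply(function(r, x) {
      v <- vapply(ctrl, win_max, numeric(1), r, x)
      if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE)
    }, rname, pos)]
  out[, low_coverage := mapply(function(r, x) {
    if (ip$rname != r) return(TRUE)
    lo <- max(ip$start, x - half); hi <- min(ip$end, x + half)
    lo > hi || all(ip$cov[(lo:hi) - ip$start + 1L] == 0L)
  }, rname, pos)]
  out[, supported := !low_coverage & !is.na(ip_max) & ip_max > min_fold &
        (is.na(control_max) | control_max <= min_fold)]
  out[]
}
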