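#' AD-ratio classification windows
#'
#' Configuration of the female/male average-depth (AD) ratio classifier. A
#' scaffold with no female coverage has AD near 0 (Y origin), equal coverage
#' gives AD near 1 (autosome), and doubled female coverage gives AD near 2
#' (X). The Y cutoff is deliberately relaxed to 0.4 because X-transposed
#' blocks of ~99% identity attract female reads and push a true Y scaffold's
#' AD upward; a strict 0.3 cutoff is kept for positive-control checks.
#'
#' @param y_max scaffolds with AD below this are called Y (default 0.4).
#' @param auto_lo,auto_hi open autosomal window (defaults 0.6, 1.4).
#' @param x_lo,x_hi X window, closed below and open above (defaults 1.6, 2.4).
#' @param strict_y_max stricter Y cutoff used for positive controls
#'   (default 0.3).
#' @param min_scaffold_len scaffolds shorter than this are left unassigned;
#'   mean depth on very short scaffolds is unstable (default 1000 bp).
#' @return an object of class `ad_config`.
#' @export
ad_config <- function(y_max = 0.4, auto_lo = 0.6, auto_hi = 1.4,
                      x_lo = 1.6, x_hi = 2.4, strict_y_max = 0.3,
                      min_scaffold_len = 1000L) {
  stopifnot(y_max < auto_lo, auto_lo < auto_hi, auto_hi < x_lo, x_lo < x_hi,
            strict_y_max <= y_max, min_scaffold_len >= 0)
  structure(list(y_max = y_max, auto_lo = auto_lo, auto_hi = auto_hi,
                 x_lo = x_lo, x_hi = x_hi, strict_y_max = strict_y_max,
                 min_scaffold_len = as.integer(min_scaffold_len)),
            class = "ad_config")
}

#' Normalised female/male depth ratio per scaffold
#'
#' `AD = mean_depth_female / (mean_depth_male * norm)` with
#' `norm = total_reads_female / total_reads_male`, so differing library sizes
#' cancel. A scaffold with zero male mean depth has an undefined ratio,
#' returned as `NA` (flagged, never an exception): absence of male data is
#' not evidence of anything.
#'
#' @param profile a depth profile from [depth_profile()].
#' @return numeric vector of AD ratios named by scaffold (`NA` = undefined).
#' @export
ad_ratio <- function(profile) {
  need <- c("scaffold_id", "mean_depth_female", "mean_depth_male")
  stopifnot(all(need %in% names(profile)))
  tot_f <- attr(profile, "total_reads_female")
  tot_m <- attr(profile, "total_reads_male")
  stopifnot(!is.null(tot_f), !is.null(tot_m), tot_f > 0, tot_m > 0)
  norm <- tot_f / tot_m
  ad <- ifelse(profile$mean_depth_male > 0,
               profile$mean_depth_female / (profile$mean_depth_male * norm),
               NA_real_)
  setNames(ad, profile$scaffold_id)
}

#' Classify scaffolds by AD ratio
#'
#' `ad < y_max` is Y; `auto_lo < ad < auto_hi` is autosomal;
#' `x_lo <= ad < x_hi` is X; anything else — including an undefined ratio —
#' is unassigned.
#'
#' @param ad numeric vector of AD ratios (`NA` = undefined).
#' @param cfg an [ad_config()].
#' @return character vector over `Y`, `A`, `X`, `unassigned`.
#' @export
classify_ad <- function(ad, cfg = ad_config()) {
  stopifnot(inherits(cfg, "ad_config"))
  out <- rep("unassigned", length(ad))
  out[!is.na(ad) & ad < cfg$y_max] <- "Y"
  out[!is.na(ad) & ad > cfg$auto_lo & ad < cfg$auto_hi] <- "A"
  out[!is.na(ad) & ad >= cfg$x_lo & ad < cfg$x_hi] <- "X"
  names(out) <- names(ad)
  out
}

#' AD classification of a whole depth profile
#'
#' Computes the AD ratio and its call for every scaffold, leaving scaffolds
#' shorter than `cfg$min_scaffold_len` unassigned.
#'
#' @param profile a depth profile from [depth_profile()].
#' @param cfg an [ad_config()].
#' @return `data.frame` with columns `scaffold_id`, `length`, `ad`, `call`.
#' @export
classify_ad_profile <- function(profile, cfg = ad_config()) {
  ad <- ad_ratio(profile)
  call <- classify_ad(ad, cfg)
  short <- profile$length < cfg$min_scaffold_len
  call[short] <- "unassigned"
  data.frame(scaffold_id = profile$scaffold_id, length = profile$length,
             ad = unname(ad), call = unname(call), stringsAsFactors = FALSE)
}
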