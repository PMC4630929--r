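# Monocot crown traits: root-tissue-angle samples along the root-tip
# paths, dominant-angle histogram bins, central-path diameters and the
# width drop-off.

# Angle of each path at the point where it first reaches depth fraction
# d of the root depth. Returns tibble(path_id, side, d, angle_deg).
sta_samples <- function(paths, profile, fracs = c(0.25, 0.5, 0.75, 0.9)) {
  r_top <- attr(profile, "r_top")
  H <- attr(profile, "H")
  rows <- lapply(seq_len(nrow(paths)), function(i) {
    pt <- paths$points[[i]]
    df <- (pt$row - r_top + 1) / H
    hit <- lapply(fracs, function(d) {
      j <- which(df >= d)[1]
      if (is.na(j)) NULL else
        tibble(path_id = paths$path_id[i], side = paths$side[i],
               d = d, angle_deg = pt$angle_deg[j])
    })
    dplyr::bind_rows(hit)
  })
  dplyr::bind_rows(rows)
}

# Dominant 10-degree histogram bins of a set of angles in [0, 90].
# Returns centers of the two most populated bins (tie -> steeper) and
# the bin index of each angle.
dominant_bins <- function(angles, bin_width = 10) {
  bin <- pmin(floor(angles / bin_width), ceiling(90 / bin_width) - 1)
  counts <- table(factor(bin, levels = 0:(ceiling(90 / bin_width) - 1)))
  ord <- order(-as.integer(counts), -as.integer(names(counts)))
  nonempty <- as.integer(counts)[ord] > 0
  centers <- (as.integer(names(counts))[ord] + 0.5) * bin_width
  list(
    dom1 = if (any(nonempty)) centers[which(nonempty)[1]] else NA_real_,
    dom2 = if (sum(nonempty) >= 2) centers[which(nonempty)[2]] else NA_real_,
    bin = bin,
    bin1 = if (any(nonempty)) as.integer(names(counts))[ord][which(nonempty)[1]] else NA_integer_,
    bin2 = if (sum(nonempty) >= 2) as.integer(names(counts))[ord][which(nonempty)[2]] else NA_integer_
  )
}

#' Monocot traits
#'
#' Root-tissue angles (`STA_*`) are path tangent angles sampled where
#' each collar-to-tip path first reaches depth fractions 0.25/0.5/0.75/
#' 0.9; per depth the paths are split by side of the collar column, the
#' more populated side giving the `_I` median and the other the `_II`.
#' `STA_DOM_I/II` are the centres of the two most populated 10-degree
#' bins of all samples (tie broken toward the steeper bin), `RTA_*` the
#' analogues using the tangent at 90% of each path's own arclength,
#' `NR_RTP_SEG_I/II` the number of paths contributing a sample to the
#' dominant bins. `CP_DIAx` are central-path diameters at depth
#' fractions, `MAX_DIA_90` the maximum diameter over the top 90% of the
#' central path's arclength, and `DROP_50` the first depth fraction past
#' the widest row at which the extent halves (1 if never).
#'
#' @param paths an `rtp_set`.
#' @param skeleton the root `root_skeleton`.
#' @param profile a [width_profile()].
#' @param scale a `scale_info`, or `NULL` for pixel units.
#' @param config a [pipeline_config()] (supplies `bin_width`).
#' @return a partial trait record.
#' @export
compute_monocot_traits <- function(paths, skeleton, profile, scale = NULL,
                                   config = pipeline_config()) {
  s <- if (!is.null(scale)) scale$pixels_per_mm else 1
  reg <- trait_registry()
  ids <- reg$trait[reg$category == "monocot"]
  if (nrow(paths) == 0) return(empty_record(ids))

  out <- list()
  sta <- sta_samples(paths, profile)
  two_sided <- nrow(paths) >= 2

  if (nrow(sta) == 0) {
    out$sta <- empty_record(grep("^STA|^RTA|^NR_RTP", ids, value = TRUE))
  } else {
    out$range <- ok_trait("STA_RANGE", diff(range(sta$angle_deg)))
    dom <- dominant_bins(sta$angle_deg, config$bin_width)
    out$dom1 <- ok_trait("STA_DOM_I", dom$dom1)
    out$dom2 <- if (two_sided) ok_trait("STA_DOM_II", dom$dom2)
                else na_trait("STA_DOM_II", "not-applicable")
    # per-depth side medians
    per_d <- lapply(c(0.25, 0.5, 0.75, 0.9), function(d) {
      sd <- sta[sta$d == d, ]
      lab <- paste0("STA_", d * 100)
      if (nrow(sd) == 0) return(empty_record(paste0(lab, c("_I", "_II"))))
      med <- tapply(sd$angle_deg, sd$side, median)
      n <- table(sd$side)
      if (length(med) == 1) {
        return(dplyr::bind_rows(
          ok_trait(paste0(lab, "_I"), as.numeric(med[1])),
          na_trait(paste0(lab, "_II"), "not-applicable")))
      }
      # _I = the larger-population side; tie -> steeper median
      first <- if (n[1] != n[2]) which.max(n) else which.max(med)
      dplyr::bind_rows(
        ok_trait(paste0(lab, "_I"), as.numeric(med[first])),
        ok_trait(paste0(lab, "_II"), as.numeric(med[-first]))
      )
    })
    out$per_d <- dplyr::bind_rows(per_d)
    # RTA: tangent at 90% of each path's own arclength
    rta <- vapply(seq_len(nrow(paths)), function(i) {
      pt <- paths$points[[i]]
      j <- which(pt$cum_px >= 0.9 * pt$cum_px[nrow(pt)])[1]
      pt$angle_deg[j]
    }, numeric(1))
    rdom <- dominant_bins(rta, config$bin_width)
    out$rta <- dplyr::bind_rows(
      ok_trait("RTA_RANGE", diff(range(rta))),
      ok_trait("RTA_DOM_I", rdom$dom1),
      if (two_sided) ok_trait("RTA_DOM_II", rdom$dom2)
      else na_trait("RTA_DOM_II", "not-applicable")
    )
    # paths assigned to a dominant bin by their median angle sample
    # (robust to single stray samples at junction crossings)
    med_bin <- tapply(sta$angle_deg, sta$path_id, function(a) {
      floor(median(a) / config$bin_width)
    })
    out$seg <- dplyr::bind_rows(
      ok_trait("NR_RTP_SEG_I", sum(med_bin == dom$bin1)),
      if (two_sided && !is.na(dom$bin2))
        ok_trait("NR_RTP_SEG_II", sum(med_bin == dom$bin2))
      else na_trait("NR_RTP_SEG_II", "not-applicable")
    )
  }

  # central-path diameters
  r_top <- attr(profile, "r_top")
  H <- attr(profile, "H")
  central <- paths$points[[which.max(paths$arclength_px)]]
  df <- (central$row - r_top + 1) / H
  cp <- vapply(c(0.25, 0.5, 0.75, 0.9), function(d) {
    j <- which(df >= d)[1]
    if (is.na(j)) NA_real_ else diameter_px(central$radius[j]) / s
  }, numeric(1))
  out$cp <- ok_trait(paste0("CP_DIA", c(25, 50, 75, 90)), cp)
  in90 <- central$cum_px <= 0.9 * central$cum_px[nrow(central)]
  out$max90 <- ok_trait("MAX_DIA_90",
                        max(diameter_px(central$radius[in90])) / s)

  # width drop-off
  ext <- profile$extent_px
  imax <- which.max(ext)
  after <- which(seq_along(ext) > imax & ext < 0.5 * max(ext))
  out$drop <- ok_trait("DROP_50",
                       if (length(after) == 0) 1.0
                       else profile$depth_frac[after[1]])

  rec <- dplyr::bind_rows(out)
  missing <- setdiff(ids, rec$trait)
  if (length(missing) > 0) rec <- dplyr::bind_rows(rec, empty_record(missing))
  rec
}
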