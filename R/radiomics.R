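#' Full radiomics profile of a VOI
#'
#' Assembles the complete per-VOI radiomics vector: the 14 shape features
#' computed once on the original mask (shape is independent of filtering and
#' discretization), plus 18 first-order and 73 texture features for every
#' combination of derived image ([build_filter_bank()]) and bin number. Under
#' the default configuration (12 images, 5 bin numbers) this is
#' `14 + 12 * 5 * 91 = 5474` features. Feature names follow
#' `<image-label>_<class>_<feature>_bin<k>` (shape: `shape_<feature>`) and the
#' ordering is deterministic.
#'
#' @param ct A [volume_grid()] (CT, or any scalar volume).
#' @param mask A non-empty [voi_mask()] on the same lattice.
#' @param cfg A [filter_config()].
#' @param bank Optional precomputed filter bank for `ct` (to share across
#'   VOIs of the same patient).
#' @return Named numeric vector (length 5474 under defaults).
#' @export
extract_radiomics_profile <- function(ct, mask, cfg = filter_config(),
                                      bank = NULL) {
  check_mask_grid(mask, ct)
  if (is.null(bank)) bank <- build_filter_bank(ct, cfg)
  out <- vector("list", 1L + length(bank) * length(cfg$bin_numbers))
  shp <- extract_shape(mask, ct$spacing)
  out[[1L]] <- stats::setNames(shp, paste0("shape_", names(shp)))
  k <- 2L
  voxvol <- prod(ct$spacing)
  for (lab in names(bank)) {
    vals <- bank[[lab]]$values[mask$indicator]
    for (nb in cfg$bin_numbers) {
      lat <- array(0L, dim(ct$values))
      lat[mask$indicator] <- discretize_fixed_bin_number(vals, nb)
      fo <- first_order_values(vals, voxvol, nb)
      tx <- texture_values(lat, as.integer(nb))
      v <- c(stats::setNames(fo, paste0("firstorder_", names(fo))), tx)
      names(v) <- sprintf("%s_%s_bin%d", lab, names(v), nb)
      out[[k]] <- v
      k <- k + 1L
    }
  }
  unlist(out)
}
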