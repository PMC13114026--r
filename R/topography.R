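#' Per-site band power by concentration step
#'
#' For every protocol step and every channel: multitaper spectrogram,
#' band-integrated density per window ([band_power()]), then the median
#' over windows — the robust per-animal summary entering group maps.
#'
#' @param rec An [eeg_recording()] carrying all montage signal channels.
#' @param protocol A [conc_protocol()].
#' @param band A [band_spec()] (default theta, 4-8 Hz).
#' @param cfg A [spectral_config()].
#' @param montage Montage whose signal channels are required.
#' @return Long data frame: `concentration`, `channel`, `power`.
#' @export
theta_site_power <- function(rec, protocol = conc_protocol(),
                             band = band_spec(), cfg = spectral_config(),
                             montage = mouse_montage()) {
  labs <- signal_labels(montage)
  missing <- setdiff(labs, rec$channel_labels)
  if (length(missing) > 0)
    stop("recording is missing montage signal channel(s): ",
         paste(missing, collapse = ", "))
  slices <- slice_by_step(rec, protocol)
  out <- list()
  for (sl in slices) {
    for (ch in labs) {
      spec <- multitaper_spectrogram(sl$recording, ch, cfg)
      out[[length(out) + 1L]] <- data.frame(
        concentration = sl$concentration, channel = ch,
        power = stats::median(band_power(spec, band)))
    }
  }
  do.call(rbind, out)
}

#' Inverse-distance-weighted interpolation on the montage plane
#'
#' Power-2 IDW over the flat AP x ML plane; exact at the nodes (a query
#' closer than 1e-9 mm to a site returns that site's value).
#'
#' @param ap_mm,ml_mm Site coordinates (mm).
#' @param values Site values.
#' @param query_ap,query_ml Query coordinates (vectors of equal length).
#' @param idw_power IDW exponent, default 2.
#' @return Numeric vector of interpolated values.
#' @export
idw_interpolate <- function(ap_mm, ml_mm, values, query_ap, query_ml,
                            idw_power = 2) {
  stopifnot(length(ap_mm) == length(values), length(query_ap) == length(query_ml))
  vapply(seq_along(query_ap), function(q) {
    d2 <- (ap_mm - query_ap[q])^2 + (ml_mm - query_ml[q])^2
    hit <- which(d2 < 1e-18)
    if (length(hit) > 0) return(values[hit[1]])
    w <- 1 / d2^(idw_power / 2)
    sum(w * values) / sum(w)
  }, 0)
}

#' Group-averaged topographic map per step
#'
#' Per site, the arithmetic mean across animals of the per-animal median
#' band power; the 2-D field is produced by inverse-distance-weighted
#' interpolation over the montage plane, masked to a 1 mm margin around
#' the rectangular hull of the signal sites. An animal missing a site is
#' (by the default policy) excluded from every step, with a message; the
#' alternative policy drops the site instead.
#'
#' @param per_animal List of per-animal site-power tables as returned by
#'   [theta_site_power()].
#' @param montage The montage (site coordinates).
#' @param grid_n Grid resolution per axis, default 41.
#' @param missing_policy `"exclude_animal"` (default) or `"exclude_site"`.
#' @return Named list (one element per step concentration) of `topo_map`
#'   objects: `site_power` (named), `grid` (`ap_mm`, `ml_mm`, `z` matrix
#'   with `NA` outside the mask), `step_concentration`, `n_animals`.
#' @export
group_topomap <- function(per_animal, montage = mouse_montage(), grid_n = 41,
                          missing_policy = c("exclude_animal", "exclude_site")) {
  missing_policy <- match.arg(missing_policy)
  stopifnot(length(per_animal) >= 1)
  labs <- signal_labels(montage)

  complete <- vapply(per_animal, function(df) all(labs %in% df$channel), TRUE)
  if (missing_policy == "exclude_animal") {
    if (any(!complete))
      message(sum(!complete), " animal(s) excluded from group map: missing sites")
    per_animal <- per_animal[complete]
    if (length(per_animal) == 0) stop("no animal carries all montage sites")
  } else {
    labs <- Reduce(intersect, lapply(per_animal, function(df) unique(df$channel)))
    if (length(labs) == 0) stop("no site is present in every animal")
  }

  steps <- sort(unique(per_animal[[1]]$concentration))
  sig <- montage[montage$role == "signal" & montage$label %in% labs, ]
  ap_r <- range(sig$ap_mm) + c(-1, 1)
  ml_r <- range(sig$ml_mm) + c(-1, 1)
  gx <- seq(ap_r[1], ap_r[2], length.out = grid_n)
  gy <- seq(ml_r[1], ml_r[2], length.out = grid_n)

  out <- lapply(steps, function(conc) {
    site_power <- vapply(labs, function(ch) {
      mean(vapply(per_animal, function(df)
        df$power[df$concentration == conc & df$channel == ch], 0))
    }, 0)
    g <- expand.grid(ap = gx, ml = gy)
    z <- idw_interpolate(sig$ap_mm, sig$ml_mm, site_power[sig$label],
                         g$ap, g$ml)
    z <- matrix(z, nrow = grid_n)
    structure(list(site_power = site_power,
                   grid = list(ap_mm = gx, ml_mm = gy, z = z),
                   step_concentration = conc,
                   n_animals = length(per_animal)),
              class = "topo_map")
  })
  names(out) <- as.character(steps)
  out
}

#' @export
print.topo_map <- function(x, ...) {
  cat(sprintf("<topo_map> %.2f vol%%, %d animal(s)\n", x$step_concentration,
              x$n_animals))
  print(round(x$site_power, 4))
  invisible(x)
}

#' Anteriorization index of a topographic map
#'
#' A scalar frontal/parietal contrast quantifying the anteriorward shift
#' of band power: `mean(F1, F2) / mean(P1, P2)`. Values above 1 indicate
#' frontal dominance. Central sites are deliberately excluded so the
#' index stays a pure frontal-parietal contrast, and the index is
#' invariant to any common rescaling of power. This measure is defined by
#' this package (topographic shifts are usually reported visually); treat
#' it as such when comparing across studies.
#'
#' @param map A `topo_map`, or a named numeric vector of site powers
#'   containing F1, F2, P1, P2.
#' @return Dimensionless ratio; `Inf` (with a warning) if parietal power
#'   is zero.
#' @export
anteriorization_index <- function(map) {
  sp <- if (inherits(map, "topo_map")) map$site_power else map
  need <- c("F1", "F2", "P1", "P2")
  if (!all(need %in% names(sp)))
    stop("site powers must include F1, F2, P1, P2")
  frontal <- mean(sp[c("F1", "F2")])
  parietal <- mean(sp[c("P1", "P2")])
  if (parietal == 0) {
    warning("zero parietal power; anteriorization index is infinite")
    return(Inf)
  }
  unname(frontal / parietal)
}

#' Anteriorization index per step, with suppression contamination flags
#'
#' Convenience wrapper: computes the index for each step of a per-site
#' power table and, when a BSR table is supplied, flags steps whose BSR
#' exceeds `bsr_cutoff` (topographic maps are interpreted before
#' burst-suppression onset; contaminated steps remain in the output but
#' are marked).
#'
#' @param site_power Long table from [theta_site_power()] (single animal)
#'   or a group average in the same shape.
#' @param bsr Optional data frame from [bsr_by_step()].
#' @param bsr_cutoff BSR (%) above which a step is flagged, default 5.
#' @return Data frame: `concentration`, `index`, and `bsr_flagged` if
#'   `bsr` was given.
#' @export
anteriorization_by_step <- function(site_power, bsr = NULL, bsr_cutoff = 5) {
  steps <- sort(unique(site_power$concentration))
  idx <- vapply(steps, function(conc) {
    sp <- site_power$power[site_power$concentration == conc]
    names(sp) <- site_power$channel[site_power$concentration == conc]
    anteriorization_index(sp)
  }, 0)
  out <- data.frame(concentration = steps, index = idx)
  if (!is.null(bsr)) {
    out$bsr_flagged <- vapply(steps, function(conc) {
      b <- bsr$bsr_percent[bsr$concentration == conc]
      length(b) > 0 && b[1] > bsr_cutoff
    }, TRUE)
  }
  out
}
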