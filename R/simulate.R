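#' Simulation parameters for synthetic TMA cores
#'
#' Parameters of the generative model behind the synthetic cohort: each bound
#' fluorescent nanoparticle is a sub-resolution point source rendered as an
#' isotropic 2-D Gaussian of width `psf_sigma_um` (the imaging point-spread
#' function, not the 130 nm particle, sets the spot width); spots fall
#' uniformly over a connected invasive-region blob at an expression-dependent
#' rate per 100 square micrometres; autofluorescence background is additive
#' Gaussian noise clipped at zero.
#'
#' Expression comes in two modes. With `spot_rate_band_per_class` set (the
#' default), each case draws its spot rate uniformly from its DAB class's
#' band, so core-level PID values span a continuum within each class — the
#' band defaults were derived analytically so the four classes span roughly
#' 0-4.3, 4.3-13.1, 13.1-32.2 and 32.2-52 (x 10^3) PID units, with class
#' minima near the corresponding cut points. With the bands set to `NULL`,
#' every core of a class uses the single rate in `spot_rate_per_class`,
#' giving well-separated, non-overlapping class supports. The methods
#' vignette derives both calibrations.
#'
#' @param pixel_size_um Physical pixel edge (um, > 0). Default 0.46, typical
#'   20x whole-slide sampling.
#' @param core_diameter_um Circular core extent (um, > 0). Default 1200.
#' @param mask_coverage Fraction of the core disc annotated invasive, in
#'   (0, 1]. Default 0.6.
#' @param spot_rate_per_class Named numeric vector, expected spot count per
#'   100 um^2 of masked area for DAB classes `"0","1+","2+","3+"`;
#'   non-decreasing in class order. Used directly when
#'   `spot_rate_band_per_class` is `NULL`, and for the negative-control rate.
#' @param spot_rate_band_per_class Named list of `c(lo, hi)` rate bands per
#'   class (per 100 um^2), or `NULL` for homogeneous per-class rates.
#' @param spot_amplitude_mean,spot_amplitude_sd Peak brightness of one spot
#'   (arbitrary intensity units); draws are clipped at zero.
#' @param psf_sigma_um Gaussian point-spread standard deviation (um).
#' @param background_mean,background_sd Additive autofluorescence noise
#'   (arbitrary units), clipped at zero per pixel.
#' @param nc_rate_scale Spot-rate scale factor applied to class-0 cores that
#'   model the no-primary-antibody negative control. Default 0.25.
#' @param seed Default integer seed used when an operation is not given one.
#' @return A validated list of class `sim_params`.
#' @export
sim_params <- function(pixel_size_um = 0.46,
                       core_diameter_um = 1200,
                       mask_coverage = 0.6,
                       spot_rate_per_class = c("0" = 1, "1+" = 11,
                                               "2+" = 43, "3+" = 90),
                       spot_rate_band_per_class = list(
                         "0" = c(0, 1.9), "1+" = c(2.2, 20.3),
                         "2+" = c(20.7, 64.8), "3+" = c(65.6, 113.3)),
                       spot_amplitude_mean = 100,
                       spot_amplitude_sd = 10,
                       psf_sigma_um = 0.3,
                       background_mean = 4,
                       background_sd = 2,
                       nc_rate_scale = 0.25,
                       seed = 1L) {
  p <- structure(
    list(pixel_size_um = pixel_size_um, core_diameter_um = core_diameter_um,
         mask_coverage = mask_coverage,
         spot_rate_per_class = spot_rate_per_class,
         spot_rate_band_per_class = spot_rate_band_per_class,
         spot_amplitude_mean = spot_amplitude_mean,
         spot_amplitude_sd = spot_amplitude_sd, psf_sigma_um = psf_sigma_um,
         background_mean = background_mean, background_sd = background_sd,
         nc_rate_scale = nc_rate_scale, seed = as.integer(seed)),
    class = "sim_params"
  )
  validate_sim_params(p)
  p
}

validate_sim_params <- function(p) {
  num1 <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x)
  if (!num1(p$pixel_size_um) || p$pixel_size_um <= 0) {
    stop("invalid parameter: pixel_size_um must be a single positive number")
  }
  if (!num1(p$core_diameter_um) || p$core_diameter_um <= 0) {
    stop("invalid parameter: core_diameter_um must be a single positive number")
  }
  if (!num1(p$mask_coverage) || p$mask_coverage <= 0 || p$mask_coverage > 1) {
    stop("invalid parameter: mask_coverage must be in (0, 1]")
  }
  r <- p$spot_rate_per_class
  if (!is.numeric(r) || !identical(sort(names(r)), sort(dab_levels()))) {
    stop("spot_rate_per_class must be a numeric vector named ",
         paste(dab_levels(), collapse = ", "))
  }
  r <- r[dab_levels()]
  if (any(r < 0)) stop("spot rates must be nonnegative")
  if (any(diff(r) < 0)) {
    stop("spot_rate_per_class must be non-decreasing in class order 0 -> 3+")
  }
  b <- p$spot_rate_band_per_class
  if (!is.null(b)) {
    if (!is.list(b) || !identical(sort(names(b)), sort(dab_levels()))) {
      stop("spot_rate_band_per_class must be a list of c(lo, hi) named ",
           paste(dab_levels(), collapse = ", "))
    }
    for (k in dab_levels()) {
      if (length(b[[k]]) != 2L || any(b[[k]] < 0) || b[[k]][1] > b[[k]][2]) {
        stop("rate band for class ", k, " must be c(lo, hi) with 0 <= lo <= hi")
      }
    }
    lows <- vapply(dab_levels(), function(k) b[[k]][1], numeric(1))
    if (any(diff(lows) < 0)) {
      stop("rate band lower edges must be non-decreasing in class order")
    }
  }
  for (f in c("spot_amplitude_mean", "spot_amplitude_sd", "psf_sigma_um",
              "background_mean", "background_sd", "nc_rate_scale")) {
    if (!num1(p[[f]]) || p[[f]] < 0) {
      stop("invalid parameter: ", f, " must be a single nonnegative number")
    }
  }
  invisible(p)
}

# Additive rendering of Gaussian spots into an n x n raster.
# sr/sc are (possibly fractional) row/col centres, amp the peak amplitudes.
# Window of +/- 5 sigma keeps the truncated mass below 4e-6 of a spot.
render_spots <- function(n, sr, sc, amp, sigma_px) {
  img <- matrix(0, n, n)
  if (length(sr) == 0L) return(img)
  w <- max(1L, ceiling(5 * sigma_px))
  off <- -w:w
  dr <- rep(off, times = length(off))
  dc <- rep(off, each = length(off))
  # chunk spots so the m x k work arrays stay modest
  chunk <- max(1L, floor(2e6 / length(dr)))
  s2 <- 2 * sigma_px^2
  for (i0 in seq(1L, length(sr), by = chunk)) {
    idx <- i0:min(i0 + chunk - 1L, length(sr))
    pr0 <- round(sr[idx]); pc0 <- round(sc[idx])
    RR <- outer(dr, pr0, "+")
    CC <- outer(dc, pc0, "+")
    W <- exp(-(sweep(RR, 2, sr[idx])^2 + sweep(CC, 2, sc[idx])^2) / s2)
    W <- sweep(W, 2, amp[idx], "*")
    keep <- RR >= 1 & RR <= n & CC >= 1 & CC <= n
    lin <- (CC[keep] - 1) * n + RR[keep]
    acc <- rowsum(W[keep], lin)
    at <- as.integer(rownames(acc))
    img[at] <- img[at] + acc[, 1L]
  }
  img
}

#' Simulate one synthetic TMA core
#'
#' Draws a connected invasive-region blob inside the core disc, a Poisson
#' number of nanoparticle spots uniform over the blob, renders each spot as a
#' 2-D Gaussian, and adds clipped-Gaussian background. Identical
#' `(params, true_class, seed)` give bit-identical output.
#'
#' The blob is kept a few point-spread widths inside the disc edge (annotated
#' invasive regions do not abut the core rim), so spot light is essentially
#' conserved within the raster.
#'
#' @param params A [sim_params()] object.
#' @param true_class DAB category driving the spot rate.
#' @param seed Integer seed (defaults to `params$seed`).
#' @param rate Optional explicit spot rate (per 100 um^2) overriding the
#'   class rate/band — used by [simulate_cohort()] for per-case expression
#'   and negative controls.
#' @param rate_scale Extra multiplier on the spot rate.
#' @param core_id Label attached to the outputs.
#' @return List with elements `image` ([core_image()]), `mask`
#'   ([invasive_mask()]) and `truth` (one-row data frame with `core_id`,
#'   `true_class`, `n_spots_drawn`).
#' @export
simulate_core <- function(params, true_class, seed = params$seed,
                          rate = NULL, rate_scale = 1,
                          core_id = NA_character_) {
  validate_sim_params(params)
  true_class <- as_dab(true_class)
  stopifnot(length(true_class) == 1L, !is.na(true_class))
  px <- params$pixel_size_um
  n <- as.integer(ceiling(params$core_diameter_um / px))
  sigma_px <- params$psf_sigma_um / px

  withr::with_seed(as.integer(seed), {
    ctr <- (n + 1) / 2
    R <- params$core_diameter_um / 2 / px
    r_mask <- R * sqrt(params$mask_coverage)
    margin <- 5 * sigma_px + 1
    max_off <- max(0, R - r_mask - margin)
    theta <- stats::runif(1, 0, 2 * pi)
    rho <- sqrt(stats::runif(1)) * max_off
    mc_r <- ctr + rho * sin(theta)
    mc_c <- ctr + rho * cos(theta)
    rows <- matrix(seq_len(n), n, n)
    cols <- matrix(seq_len(n), n, n, byrow = TRUE)
    msk <- (rows - mc_r)^2 + (cols - mc_c)^2 <= r_mask^2

    area_um2 <- sum(msk) * px^2
    if (is.null(rate)) {
      b <- params$spot_rate_band_per_class
      rate <- if (is.null(b)) {
        params$spot_rate_per_class[[true_class]]
      } else {
        stats::runif(1, b[[true_class]][1], b[[true_class]][2])
      }
    }
    n_spots <- stats::rpois(1, rate * rate_scale * area_um2 / 100)

    img <- matrix(0, n, n)
    if (n_spots > 0) {
      at <- sample(which(msk), n_spots, replace = TRUE)
      sr <- ((at - 1L) %% n) + 1L + stats::runif(n_spots, -0.5, 0.5)
      sc <- ((at - 1L) %/% n) + 1L + stats::runif(n_spots, -0.5, 0.5)
      amp <- pmax(stats::rnorm(n_spots, params$spot_amplitude_mean,
                               params$spot_amplitude_sd), 0)
      img <- img + render_spots(n, sr, sc, amp, sigma_px)
    }
    if (params$background_mean > 0 || params$background_sd > 0) {
      img <- img + matrix(pmax(stats::rnorm(n * n, params$background_mean,
                                            params$background_sd), 0), n, n)
    }

    list(
      image = core_image(img, px, core_id),
      mask = invasive_mask(msk, core_id),
      truth = data.frame(core_id = core_id, true_class = true_class,
                         n_spots_drawn = n_spots, stringsAsFactors = FALSE)
    )
  })
}

#' Valid exclusion annotations
#'
#' @return Character vector of recognized exclusion reasons; `"none"` marks an
#'   analyzable core.
#' @export
exclusion_reasons <- function() {
  c("none", "dcis", "fixation", "cytoplasmic", "no_cancer", "peeling")
}

#' Reference 208-core TMA exclusion plan
#'
#' The pathologist exclusion annotations of the reference 104-case,
#' duplicate-core breast-cancer TMA used throughout the package examples:
#' 23 cores of ductal carcinoma in situ, 8 with fixation too poor to judge,
#' 2 with cytoplasmic staining, 3 with no cancer, and 2 peeled cores — 38 in
#' total.
#'
#' @return Named list mapping exclusion reason to core-ID character vector.
#' @export
tma208_exclusion_plan <- function() {
  list(
    dcis = c("A5", "A6", "A11", "A12", "C1", "C2", "C10", "C14", "C15",
             "C16", "D7", "D9", "D10", "F8", "G15", "G16", "H3", "H4",
             "I7", "I8", "J3", "M15", "M16"),
    fixation = c("F3", "F4", "E13", "E14", "K11", "K12", "L1", "L2"),
    cytoplasmic = c("L7", "L8"),
    no_cancer = c("H15", "K15", "K16"),
    peeling = c("B4", "E5")
  )
}

#' Reference 208-core class composition
#'
#' Default per-class core counts for the simulated cohort, chosen so the
#' analyzable subset after the reference exclusions carries roughly 103 DAB-0
#' cores (the composition the assay was characterized on) with a realistic
#' 1+/2+/3+ split.
#'
#' @return Named integer vector over `"0","1+","2+","3+"` summing to 208.
#' @export
tma208_class_counts <- function() {
  c("0" = 126L, "1+" = 36L, "2+" = 24L, "3+" = 22L)
}

#' Design a synthetic cohort (metadata only, no rasters)
#'
#' Lays out `sum(class_counts)` cores on a letter-row/number-column TMA grid
#' (16 columns), pairs consecutive cores into duplicate-core cases, assigns a
#' DAB class per case by a seeded permutation, simulates two pathologists'
#' readings, applies the exclusion plan, and appends negative-control records
#' (row `Z`).
#'
#' When `params` carries per-class rate bands, each case also draws its
#' expression level (spot rate) uniformly from its class band, and each
#' pathologist categorizes a log-normally perturbed copy of that expression
#' (`reader_sd`), so disagreements concentrate near class boundaries as they
#' do in visual scoring. Without bands, the second reading shifts one class
#' with flat probability `disagree_prob`.
#'
#' @param class_counts Named count vector over DAB classes (case pairs share a
#'   class when counts are even).
#' @param n_negative_controls Number of no-primary-antibody control cores.
#' @param exclusion_plan Named list, reason -> core IDs, as in
#'   [tma208_exclusion_plan()].
#' @param seed Integer seed.
#' @param params Optional [sim_params()]; enables expression-based readings.
#' @param reader_sd Log-normal sd of each pathologist's perceived expression
#'   (band mode only).
#' @param disagree_prob Flat disagreement probability (no-band mode only).
#' @return Data frame with columns `core_id`, `case_id`, `true_class`,
#'   `is_negative_control`, `exclusion_reason`, `n_spots_drawn` (`NA` until
#'   rasters are simulated), `case_rate` (`NA` without bands),
#'   `dab_score_p1`, `dab_score_p2`.
#' @export
cohort_design <- function(class_counts, n_negative_controls = 0L,
                          exclusion_plan = list(), seed = 1L,
                          params = NULL, reader_sd = 0.1,
                          disagree_prob = 0.05) {
  stopifnot(is.numeric(class_counts), all(class_counts >= 0))
  cls_names <- as_dab(names(class_counts))
  n_total <- as.integer(sum(class_counts))
  if (n_total < 1L) stop("class_counts must produce at least one core")
  n_cols <- 16L
  n_rows <- ceiling(n_total / n_cols)
  if (n_rows > 25L) stop("cohort too large for a letter-row grid")
  pos <- seq_len(n_total)
  core_id <- paste0(LETTERS[(pos - 1L) %/% n_cols + 1L],
                    (pos - 1L) %% n_cols + 1L)
  case_id <- (pos + 1L) %/% 2L
  n_cases <- max(case_id)
  bands <- if (is.null(params)) NULL else params$spot_rate_band_per_class

  withr::with_seed(as.integer(seed), {
    cls <- rep(cls_names, class_counts)
    rank_of_case <- match(seq_len(n_cases), sample.int(n_cases))
    true_class <- character(n_total)
    for (j in seq_len(n_cases)) {
      k <- rank_of_case[j]
      i1 <- 2L * j - 1L
      true_class[i1] <- cls[2L * k - 1L]
      if (2L * j <= n_total) true_class[2L * j] <- cls[min(2L * k, n_total)]
    }
    if (is.null(bands)) {
      case_rate <- rep(NA_real_, n_total)
      p1 <- true_class
      o <- dab_ordinal(true_class)
      shift <- stats::runif(n_total) < disagree_prob
      dirn <- ifelse(stats::runif(n_total) < 0.5, -1L, 1L)
      o2 <- pmin(pmax(o + ifelse(shift, dirn, 0L), 0L), 3L)
      p2 <- dab_levels()[o2 + 1L]
    } else {
      # class edges in rate space: a reading is the band a perceived rate
      # falls into
      edges <- vapply(dab_levels()[-1], function(k) bands[[k]][1], numeric(1))
      rate_by_case <- vapply(seq_len(n_cases), function(j) {
        b <- bands[[true_class[2L * j - 1L]]]
        stats::runif(1, b[1], b[2])
      }, numeric(1))
      case_rate <- rate_by_case[case_id]
      perceive <- function(r, eps) {
        dab_levels()[findInterval(r * exp(eps), edges) + 1L]
      }
      p1 <- perceive(case_rate, stats::rnorm(n_total, 0, reader_sd))
      p2 <- perceive(case_rate, stats::rnorm(n_total, 0, reader_sd))
    }
  })

  df <- data.frame(
    core_id = core_id, case_id = case_id, true_class = true_class,
    is_negative_control = FALSE, exclusion_reason = "none",
    n_spots_drawn = NA_integer_, case_rate = case_rate,
    dab_score_p1 = p1, dab_score_p2 = p2,
    stringsAsFactors = FALSE
  )

  if (length(exclusion_plan) > 0) {
    if (is.null(names(exclusion_plan)) ||
        !all(names(exclusion_plan) %in% setdiff(exclusion_reasons(), "none"))) {
      stop("exclusion_plan names must be exclusion reasons: ",
           paste(setdiff(exclusion_reasons(), "none"), collapse = ", "))
    }
    ids <- unlist(exclusion_plan, use.names = FALSE)
    if (anyDuplicated(ids)) {
      stop("exclusion_plan lists core IDs more than once: ",
           paste(unique(ids[duplicated(ids)]), collapse = ", "))
    }
    for (reason in names(exclusion_plan)) {
      for (id in exclusion_plan[[reason]]) {
        at <- match(id, df$core_id)
        if (is.na(at)) stop("exclusion_plan names core ", id,
                            " which is not in the generated grid")
        df$exclusion_reason[at] <- reason
      }
    }
  }

  if (n_negative_controls > 0) {
    nc <- data.frame(
      core_id = paste0("Z", seq_len(n_negative_controls)),
      case_id = NA_integer_, true_class = "0", is_negative_control = TRUE,
      exclusion_reason = "none", n_spots_drawn = NA_integer_,
      case_rate = NA_real_,
      dab_score_p1 = NA_character_, dab_score_p2 = NA_character_,
      stringsAsFactors = FALSE
    )
    df <- rbind(df, nc)
  }
  df
}

#' Simulate a full synthetic cohort
#'
#' [cohort_design()] plus rasters: every record gets a fluorescence image and
#' invasive mask from [simulate_core()]; duplicate cores of a case share the
#' case's expression level; negative controls run at the class-0 point rate
#' scaled by `params$nc_rate_scale`. Reproducible: the same
#' `(params, ..., seed)` give bit-identical cohorts.
#'
#' @inheritParams cohort_design
#' @param params A [sim_params()] object.
#' @return List with `cores` (named list of `list(image, mask)` keyed by
#'   core ID) and `truth` (the design data frame with `n_spots_drawn` filled).
#' @export
simulate_cohort <- function(params, class_counts, n_negative_controls = 0L,
                            exclusion_plan = list(), seed = params$seed,
                            reader_sd = 0.1, disagree_prob = 0.05) {
  validate_sim_params(params)
  truth <- cohort_design(class_counts, n_negative_controls, exclusion_plan,
                         seed = seed, params = params, reader_sd = reader_sd,
                         disagree_prob = disagree_prob)
  n <- nrow(truth)
  child <- withr::with_seed(as.integer(seed),
                            sample.int(.Machine$integer.max, n))
  nc_rate <- params$nc_rate_scale * params$spot_rate_per_class[["0"]]
  cores <- vector("list", n)
  names(cores) <- truth$core_id
  for (i in seq_len(n)) {
    rate <- if (truth$is_negative_control[i]) {
      nc_rate
    } else if (!is.na(truth$case_rate[i])) {
      truth$case_rate[i]
    } else {
      NULL # class point rate inside simulate_core
    }
    sim <- simulate_core(params, truth$true_class[i], seed = child[i],
                         rate = rate, core_id = truth$core_id[i])
    cores[[i]] <- list(image = sim$image, mask = sim$mask)
    truth$n_spots_drawn[i] <- sim$truth$n_spots_drawn
  }
  list(cores = cores, truth = truth)
}
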