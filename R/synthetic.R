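# Synthetic-data generators: a parametric GCR-like flux spectrum, noisy
# cross-section measurement sets drawn from the geometric model, and
# Bragg-curve fixtures with constructed ground truth. All generators are pure
# functions of (parameters, seed).

#' Shape parameters of the synthetic GCR spectrum
#'
#' The differential flux per species is a power law in total energy per
#' nucleon with a solar-modulation-like low-energy roll-off:
#' phi(E) proportional to (E/(E + Phi))^a x ((E + m)/1000)^(-gamma), with
#' gamma the spectral index (default 2.7, the conventional GCR value),
#' a the roll-off exponent and Phi the modulation parameter (MV-like;
#' larger values harden the spectrum by suppressing the sub-GeV flux, as at
#' solar maximum). Default abundances put 87% of the flux in hydrogen, 12% in
#' helium and 1% in the heavy ions C, O, Mg, Si, Fe, split so that the
#' dose-weighted mean heavy charge is about 10; they are a documented
#' stand-in for a full GCR composition model and are fully tunable.
#'
#' @param spectral_index High-energy power-law index (> 1).
#' @param rolloff_exponent Low-energy roll-off exponent a (> 0).
#' @param modulation Modulation parameter Phi, MeV-like scale (>= 0).
#' @param abundances data.frame with columns `z`, `a`, `fraction` (positive;
#'   normalised internally).
#' @return Object of class `spectrum_shape_params`.
#' @export
spectrum_shape_params <- function(spectral_index = 2.7, rolloff_exponent = 2,
                                  modulation = 600, abundances = NULL) {
  if (spectral_index <= 1) stop("spectral_index must be > 1")
  if (rolloff_exponent <= 0) stop("rolloff_exponent must be positive")
  if (modulation < 0) stop("modulation must be >= 0")
  if (is.null(abundances)) {
    abundances <- data.frame(
      z = c(1, 2, 6, 8, 12, 14, 26),
      a = c(1, 4, 12, 16, 24, 28, 56),
      fraction = c(0.87, 0.12, 0.004, 0.0035, 0.001, 0.0008, 0.0007)
    )
  }
  if (any(abundances$fraction <= 0) || sum(abundances$fraction) <= 0)
    stop("abundances must be positive (unnormalizable)")
  abundances$fraction <- abundances$fraction / sum(abundances$fraction)
  structure(list(spectral_index = spectral_index,
                 rolloff_exponent = rolloff_exponent,
                 modulation = modulation, abundances = abundances),
            class = "spectrum_shape_params")
}

#' Generate a synthetic GCR-like flux spectrum
#'
#' Tabulates the parametric differential flux on a log-spaced energy grid for
#' every species in the abundance table, normalised so the total
#' energy-integrated flux is 1 (relative fluence units). Deterministic for
#' given parameters; `seed` is accepted for interface uniformity but unused.
#'
#' @param params A [spectrum_shape_params()].
#' @param e_min,e_max Energy grid limits, MeV/nuc.
#' @param n_grid Grid points per species.
#' @param seed Ignored (generator is deterministic).
#' @return data.frame of class `flux_spectrum` with columns `z`, `a`,
#'   `energy_mev_per_nuc`, `flux_per_cm2_mev`.
#' @export
#' @examples
#' sp <- make_gcr_spectrum()
#' sum(spectrum_species_fractions(sp)[c("1", "2")])  # H+He ~ 0.99
make_gcr_spectrum <- function(params = spectrum_shape_params(),
                              e_min = 10, e_max = 1e5, n_grid = 160,
                              seed = NULL) {
  stopifnot(inherits(params, "spectrum_shape_params"))
  Eg <- exp(seq(log(e_min), log(e_max), length.out = n_grid))
  m <- .M_NUCLEON
  # roll-off anchored at 10 GeV/nuc: modulation reshapes only the low-energy
  # flux and leaves the high-energy tail fixed (total flux then decreases
  # with increasing modulation, as in the heliosphere)
  e_anchor <- 1e4
  roll <- (Eg / (Eg + params$modulation))^params$rolloff_exponent /
    (e_anchor / (e_anchor + params$modulation))^params$rolloff_exponent
  shape <- roll * ((Eg + m) / 1000)^(-params$spectral_index)
  tail_shape <- ((Eg + m) / 1000)^(-params$spectral_index)
  norm <- sum(diff(Eg) * (tail_shape[-n_grid] + tail_shape[-1]) / 2)
  ab <- params$abundances
  out <- do.call(rbind, lapply(seq_len(nrow(ab)), function(i)
    data.frame(z = ab$z[i], a = ab$a[i], energy_mev_per_nuc = Eg,
               flux_per_cm2_mev = ab$fraction[i] * shape / norm)))
  attr(out, "params") <- params
  class(out) <- c("flux_spectrum", "data.frame")
  out
}

#' Energy-integrated flux fraction per species
#'
#' @param spectrum A `flux_spectrum`.
#' @return Named vector (names = charge numbers) summing to 1.
#' @export
spectrum_species_fractions <- function(spectrum) {
  sp <- split(spectrum, spectrum$z)
  v <- vapply(sp, function(d) {
    E <- d$energy_mev_per_nuc; f <- d$flux_per_cm2_mev
    sum(diff(E) * (f[-length(f)] + f[-1]) / 2)
  }, numeric(1))
  v / sum(v)
}

#' Sample primaries from a flux spectrum
#'
#' Energies are drawn from the tabulated differential flux (log-uniform
#' within grid bins). Species counts are allocated *stratified*: each species
#' receives its expected share of the n primaries (largest-remainder
#' rounding) rather than a multinomial draw. This is a variance-reduction
#' choice: dosimetric summaries are dominated by the few heavy ions, and
#' Poisson noise on their counts would otherwise swamp the quantities of
#' interest at desk-scale n.
#'
#' @param spectrum A `flux_spectrum`.
#' @param n Number of particles.
#' @param seed Optional integer seed.
#' @return data.frame: `z`, `a`, `energy_mev_per_nuc` (shuffled).
#' @export
sample_spectrum <- function(spectrum, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (nrow(spectrum) == 0) stop("empty spectrum")
  sp <- split(spectrum, paste(spectrum$z, spectrum$a))
  frac <- vapply(sp, function(d) {
    E <- d$energy_mev_per_nuc; f <- d$flux_per_cm2_mev
    sum(diff(E) * (f[-length(f)] + f[-1]) / 2)
  }, numeric(1))
  frac <- frac / sum(frac)
  counts <- floor(n * frac)
  rem <- n - sum(counts)
  if (rem > 0) {
    extra <- order(n * frac - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1L
  }
  out <- do.call(rbind, lapply(seq_along(sp), function(i) {
    if (counts[i] == 0) return(NULL)
    d <- sp[[i]]
    E <- d$energy_mev_per_nuc; f <- d$flux_per_cm2_mev
    nb <- length(E) - 1
    wb <- diff(E) * (f[-length(f)] + f[-1]) / 2
    cw <- c(0, cumsum(wb)) / sum(wb)
    # stratified inverse-CDF draw: one jittered quantile per particle
    m <- counts[i]
    u <- (seq_len(m) - stats::runif(m)) / m
    b <- pmin(findInterval(u, cw, rightmost.closed = TRUE), nb)
    frac <- (u - cw[b]) / (cw[b + 1] - cw[b])
    data.frame(z = d$z[1], a = d$a[1],
               energy_mev_per_nuc = exp(log(E[b]) + frac * (log(E[b + 1]) - log(E[b]))))
  }))
  out[sample.int(nrow(out)), , drop = FALSE]
}

#' Default projectile/target pairs for cross-section studies
#'
#' Five projectile species crossed with the six standard target elements
#' (H, C, Al, Cu, Sn, Pb): 30 pairs, mirroring the scope of published
#' charge-changing data sets.
#'
#' @return data.frame: `z_proj`, `a_proj`, `target_symbol`, `a_targ`.
#' @export
default_projectile_target_pairs <- function() {
  proj <- data.frame(z_proj = c(6, 8, 12, 14, 26),
                     a_proj = c(12, 16, 24, 28, 56))
  targ <- data.frame(target_symbol = c("H", "C", "Al", "Cu", "Sn", "Pb"),
                     a_targ = c(1, 12, 27, 64, 119, 207))
  out <- merge(proj, targ)
  out[order(out$z_proj, out$a_targ), c("z_proj", "a_proj", "target_symbol", "a_targ")]
}

#' Generate a noisy synthetic cross-section data set
#'
#' Records lie on the geometric-model surface at the `truth` parameters, with
#' multiplicative Gaussian noise; reported errors are `noise_fraction` times
#' the reported cross section.
#'
#' @param truth A [geometric_params()].
#' @param pairs Projectile/target pairs
#'   ([default_projectile_target_pairs()]).
#' @param noise_fraction Relative noise (>= 0).
#' @param seed Optional integer seed.
#' @param energy Nominal beam energy recorded, MeV/nuc.
#' @return data.frame of cross-section records (see [read_xsec_csv()]).
#' @export
make_xsec_dataset <- function(truth = geometric_params(),
                              pairs = default_projectile_target_pairs(),
                              noise_fraction = 0.1, seed = NULL,
                              energy = 600) {
  if (noise_fraction < 0) stop("noise_fraction must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  model <- sigma_cc(pairs$a_proj, pairs$a_targ, truth)
  sigma <- model * (1 + stats::rnorm(nrow(pairs), 0, noise_fraction))
  sigma <- pmax(sigma, 0.05 * model)
  data.frame(
    z_proj = pairs$z_proj, a_proj = pairs$a_proj,
    target_symbol = pairs$target_symbol, a_targ = pairs$a_targ,
    energy_mev_per_nuc = energy,
    sigma_mb = sigma, sigma_err_mb = noise_fraction * sigma
  )
}

#' Construct a Bragg-curve fixture with known ground truth
#'
#' A smooth rise-peak-distal-tail curve: entrance ratio exactly 1, a
#' power-law rise to `peak_ratio` at `peak_depth` (placed exactly on the
#' depth grid), and an exponential distal tail, with optional multiplicative
#' Gaussian noise.
#'
#' @param peak_depth Peak location, g cm^-2 (> 0).
#' @param peak_ratio Peak ionization ratio.
#' @param noise_fraction Relative noise (>= 0).
#' @param seed Optional integer seed.
#' @param step Grid spacing, g cm^-2.
#' @param tail_length Distal tail extent, g cm^-2.
#' @param tail_fraction Ratio just past the peak relative to `peak_ratio`.
#' @return List of class `bragg_curve` with `depth` and `ionization_ratio`
#'   and attribute-free constructed truth in `truth`.
#' @export
make_bragg_fixture <- function(peak_depth, peak_ratio = 6.5,
                               noise_fraction = 0, seed = NULL,
                               step = 0.05, tail_length = 3,
                               tail_fraction = 0.25) {
  if (peak_depth <= 0) stop("peak_depth must be positive")
  if (!is.null(seed)) set.seed(seed)
  rise <- seq(0, peak_depth, by = step)
  if (rise[length(rise)] < peak_depth) rise <- c(rise, peak_depth)
  tail <- peak_depth + seq(step, tail_length, by = step)
  d <- c(rise, tail)
  r <- c(1 + (peak_ratio - 1) * (rise / peak_depth)^6,
         tail_fraction * peak_ratio * exp(-(tail - peak_depth) / 1.0))
  if (noise_fraction > 0)
    r <- r * (1 + stats::rnorm(length(r), 0, noise_fraction))
  structure(list(depth = d, ionization_ratio = r, step = step,
                 truth = list(peak_depth = peak_depth, peak_ratio = peak_ratio)),
            class = "bragg_curve")
}

#' Write a flux spectrum to CSV
#'
#' Columns: z, a, energy_mev_per_nuc, flux_per_cm2_mev.
#'
#' @param spectrum A `flux_spectrum`.
#' @param path CSV path.
#' @export
write_spectrum_csv <- function(spectrum, path) {
  utils::write.csv(as.data.frame(spectrum), path, row.names = FALSE)
  invisible(spectrum)
}

#' @rdname write_spectrum_csv
#' @export
read_spectrum_csv <- function(path) {
  out <- utils::read.csv(path)
  class(out) <- c("flux_spectrum", "data.frame")
  out
}
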