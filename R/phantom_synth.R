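# Synthetic data: geometric sphere phantoms with closed-form coverage
# oracles, and a seeded statistical cohort simulator mirroring the schema
# of the clinical per-tumor margin profiles.

#' Voxelized two-sphere phantom
#'
#' Builds an `ablation_case` from two analytic spheres: a tumor of radius
#' `tumor_radius` at the grid center and an ablation of radius
#' `ablation_radius` whose center is displaced by `center_offset` mm along
#' the first axis. Voxelization is by center inclusion (a voxel is
#' foreground iff its center lies within the sphere, boundary included);
#' the construction is fully deterministic.
#'
#' @param tumor_radius,ablation_radius Radii in mm, > 0.
#' @param center_offset Displacement of the ablation center along axis 1,
#'   mm. Offset phantoms produce one-sided coverage deficits, reaching all
#'   partial-coverage completeness classes.
#' @param spacing Voxel spacing in mm (default 1 x 1 x 3, a typical CT
#'   in-plane resolution with 3-mm slices).
#' @param pad Empty border in mm beyond the spheres; must be at least the
#'   largest margin later evaluated, or [assess_case()] will refuse to
#'   expand past the array face.
#' @param case_id Identifier for the case.
#' @return An `ablation_case`.
#' @export
make_sphere_phantom <- function(tumor_radius, ablation_radius,
                                center_offset = 0,
                                spacing = c(1, 1, 3), pad = 12,
                                case_id = "phantom") {
  stopifnot(tumor_radius > 0, ablation_radius > 0, pad >= 0,
            center_offset >= 0)
  half <- c(max(tumor_radius, ablation_radius + center_offset),
            max(tumor_radius, ablation_radius),
            max(tumor_radius, ablation_radius)) + pad
  n <- 2L * floor(half / spacing) + 1L
  ctr <- (n + 1) / 2
  ax <- lapply(1:3, function(k) (seq_len(n[k]) - ctr[k]) * spacing[k])
  # squared distance fields to the two centers, built separably
  sq <- function(off) {
    outer(outer((ax[[1]] - off)^2, ax[[2]]^2, `+`), ax[[3]]^2, `+`)
  }
  tum <- sq(0) <= tumor_radius^2 + 1e-9
  abl <- sq(center_offset) <= ablation_radius^2 + 1e-9
  validate_pair(voxel_grid(array(as.integer(tum), dim = n), spacing),
                voxel_grid(array(as.integer(abl), dim = n), spacing),
                case_id = case_id)
}

# volume of the intersection lens of two spheres (radii r1, r2, center
# distance d); closed form via spherical caps
.lens_volume <- function(r1, r2, d) {
  if (d >= r1 + r2) return(0)
  if (d <= abs(r1 - r2)) return(4 / 3 * pi * min(r1, r2)^3)
  pi * (r1 + r2 - d)^2 *
    (d^2 + 2 * d * (r1 + r2) - 3 * (r1 - r2)^2) / (12 * d)
}

#' Continuous-space unablated margin fraction for sphere phantoms
#'
#' Closed-form oracle for [unablated_margin_percent()] on two-sphere
#' geometry: the m-mm shell around a tumor of radius `rt` has volume
#' (4/3)pi((rt+m)^3 - rt^3); the part covered by an ablation sphere of
#' radius `ra` displaced by `d` is the difference of two sphere-sphere
#' intersection lenses. Voxelized results converge to this value as voxel
#' size shrinks.
#'
#' @param rt Tumor radius, mm.
#' @param ra Ablation radius, mm.
#' @param d Center offset, mm, >= 0.
#' @param m Margin, mm, > 0.
#' @return U_m in percent, in [0, 100].
#' @export
analytic_margin_fraction <- function(rt, ra, d, m) {
  stopifnot(rt > 0, ra > 0, m > 0, d >= 0)
  v_shell <- 4 / 3 * pi * ((rt + m)^3 - rt^3)
  covered <- .lens_volume(rt + m, ra, d) - .lens_volume(rt, ra, d)
  100 * min(1, max(0, (v_shell - covered) / v_shell))
}

#' Simulate a cohort of margin profiles with LTP outcomes
#'
#' Statistical stand-in for a treated-tumor cohort, generated directly in
#' percentage space (no masks) so that hundreds of cases are cheap. Each
#' case carries a radial coverage-deficit model: the ablation covers the
#' tumor everywhere, out to a depth `D` mm over a solid-angle fraction `f`
#' of directions and beyond the largest margin elsewhere. The unablated
#' percentage at margin m is then
#' `U_m = 100 f ((rt+m)^3 - (rt+D)^3) / ((rt+m)^3 - rt^3)` for m > D and 0
#' otherwise, which is non-decreasing in m — the same nesting the clinical
#' profiles show. Local tumor progression follows a threshold rule on the
#' profile: LTP iff `U_{m_star} > tau`, flipped with probability `eps`
#' (Bernoulli noise). Times to LTP are log-normal (positive, right-skewed);
#' non-LTP cases are administratively censored at a uniform follow-up time.
#'
#' @param n_cases Number of tumors.
#' @param margins Margins evaluated, mm.
#' @param m_star Reference margin of the outcome rule, mm (default 6).
#' @param tau LTP threshold on `U_{m_star}` in percent (default 10, the
#'   boundary of the >=90%-coverage classes).
#' @param eps Probability of flipping the rule's outcome (default 0.05).
#' @param deficit_meanlog,deficit_sdlog Log-normal parameters of the
#'   coverage depth D, mm.
#' @param frac_shape1,frac_shape2 Beta parameters of the solid-angle
#'   fraction f.
#' @param p_incomplete Fraction of cases with residual (unablated) tumor;
#'   these have D = 0 and a positive residual percentage.
#' @param time_meanlog,time_sdlog Log-normal parameters of time to LTP in
#'   months (defaults give mean 18.3, SD 11.9 months).
#' @param fu_min,fu_max Uniform administrative censoring window, months.
#' @param seed Integer seed; identical seed and parameters reproduce the
#'   cohort exactly.
#' @return Data frame with columns `case_id`, `ltp`, `time_months`,
#'   `residual_pct`, `u1`..`u10` (per requested margin), `size_mm`, `age`,
#'   `male`, `subcapsular`, `vessel`, `organ`, `prior_ctx`, `prior_hr`,
#'   `adjuvant_ctx`. The seed is recorded in `attr(, "seed")`.
#' @export
simulate_cohort <- function(n_cases = 76, margins = 1:10,
                            m_star = 6, tau = 10, eps = 0.05,
                            deficit_meanlog = log(4), deficit_sdlog = 0.6,
                            frac_shape1 = 2, frac_shape2 = 6,
                            p_incomplete = 2 / 76,
                            time_meanlog = 2.7305, time_sdlog = 0.5939,
                            fu_min = 12, fu_max = 60,
                            seed = NULL) {
  stopifnot(n_cases >= 0, all(margins > 0), m_star %in% margins,
            tau >= 0, eps >= 0, eps <= 1, fu_min > 0, fu_max >= fu_min)
  if (!is.null(seed)) set.seed(seed)
  un <- paste0("u", margins)
  if (n_cases == 0) {
    out <- as.data.frame(c(
      list(case_id = character(), ltp = integer(), time_months = numeric(),
           residual_pct = numeric()),
      setNames(rep(list(numeric()), length(margins)), un),
      list(size_mm = numeric(), age = integer(), male = integer(),
           subcapsular = integer(), vessel = integer(), organ = integer(),
           prior_ctx = integer(), prior_hr = integer(),
           adjuvant_ctx = integer())))
    attr(out, "seed") <- seed
    return(out)
  }
  size_mm <- pmin(pmax(rlnorm(n_cases, log(20), 0.5), 3), 75)
  rt <- size_mm / 2
  incomplete <- rbinom(n_cases, 1, p_incomplete)
  residual_pct <- ifelse(incomplete == 1, runif(n_cases, 1, 70), 0)
  D <- ifelse(incomplete == 1, 0, rlnorm(n_cases, deficit_meanlog, deficit_sdlog))
  f <- rbeta(n_cases, frac_shape1, frac_shape2)
  u <- sapply(margins, function(m) {
    shell <- (rt + m)^3 - rt^3
    uncov <- pmax(0, (rt + m)^3 - (rt + pmin(D, m))^3)
    # ratio before product: keeps profiles exactly constant (hence
    # monotone) when the deficit spans the whole shell
    100 * f * (uncov / shell)
  })
  u <- matrix(u, nrow = n_cases,
              dimnames = list(NULL, un))
  rule <- u[, paste0("u", m_star)] > tau
  flip <- runif(n_cases) < eps
  ltp <- as.integer(xor(rule, flip))
  t_event <- pmin(pmax(rlnorm(n_cases, time_meanlog, time_sdlog), 0.1), fu_max)
  t_cens <- runif(n_cases, fu_min, fu_max)
  time_months <- ifelse(ltp == 1, t_event, t_cens)
  out <- cbind(
    data.frame(case_id = sprintf("sim%03d", seq_len(n_cases)),
               ltp = ltp, time_months = time_months,
               residual_pct = residual_pct, stringsAsFactors = FALSE),
    as.data.frame(u),
    data.frame(size_mm = size_mm,
               age = as.integer(pmin(pmax(round(rnorm(n_cases, 64.5, 10)), 31), 87)),
               male = rbinom(n_cases, 1, 52 / 76),
               subcapsular = rbinom(n_cases, 1, 25 / 76),
               vessel = rbinom(n_cases, 1, 23 / 76),
               organ = rbinom(n_cases, 1, 11 / 76),
               prior_ctx = rbinom(n_cases, 1, 55 / 76),
               prior_hr = rbinom(n_cases, 1, 24 / 76),
               adjuvant_ctx = rbinom(n_cases, 1, 41 / 76)))
  attr(out, "seed") <- seed
  out
}

.cohort_required_cols <- function(margins = 1:10) {
  c("case_id", "ltp", "time_months", "residual_pct", paste0("u", margins))
}

#' Write a cohort table to CSV
#' @param cohort Cohort data frame (see [simulate_cohort()]).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_cohort_csv <- function(cohort, path) {
  write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' Read and schema-check a cohort CSV
#'
#' @param path CSV path.
#' @param margins Margins whose `u<m>` columns must be present.
#' @return Data frame; errors name any missing column.
#' @export
read_cohort_csv <- function(path, margins = 1:10) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(.cohort_required_cols(margins), names(df))
  if (length(missing))
    stop("cohort CSV is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (any(df$time_months <= 0))
    stop("cohort CSV: time_months must be positive", call. = FALSE)
  if (!all(df$ltp %in% c(0L, 1L)))
    stop("cohort CSV: ltp must be 0/1", call. = FALSE)
  df
}
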