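#' The packaged 124-species lipid panel
#'
#' A Biocrates p180-style targeted panel of 124 species across five classes
#' (50 PC, 22 LPC, 20 SM, 18 PC O-, 14 CAR), each with a synthetic
#' class-typical baseline (log2 median control concentration, uM scale).
#'
#' @param path Path to a panel TSV (`name`, `lipid_class`, `baseline_log2`);
#'   `NULL` loads the packaged default.
#' @return `panel_info()`: the panel data frame. `default_panel()`: the
#'   character vector of species names.
#' @export
panel_info <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "lipid_panel.tsv", package = "lipidshift")
  p <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  stopifnot(all(c("name", "lipid_class", "baseline_log2") %in% names(p)),
            !anyDuplicated(p$name))
  p
}

#' @rdname panel_info
#' @export
default_panel <- function(path = NULL) panel_info(path)$name

#' Describe a case-control cohort design
#'
#' @param n_case,n_control Group sizes (defaults 30 and 11, the study design
#'   the generator emulates).
#' @param panel Character vector of species names; all must parse.
#' @param seed Integer seed used by [simulate_cohort()] unless overridden.
#' @return A list of class `cohort_design`.
#' @export
cohort_design <- function(n_case = 30, n_control = 11, panel = default_panel(),
                          seed = 1L) {
  stopifnot(n_case >= 2, n_control >= 2, length(panel) >= 2,
            !anyDuplicated(panel))
  invisible(lapply(panel, parse_lipid_name))  # every name must parse
  structure(list(n_case = as.integer(n_case), n_control = as.integer(n_control),
                 panel = panel, seed = as.integer(seed)),
            class = "cohort_design")
}

#' Specify group effects for the generator
#'
#' @param shifts Named numeric vector of log2 case-minus-control shifts;
#'   species not named get shift 0.
#' @param noise_sigma Standard deviation of log2 abundance within group
#'   (default 0.5, so a shift of 1 is a standardized effect of 2).
#' @param baseline Named numeric vector of log2 median control abundances;
#'   `NULL` uses the packaged panel baselines.
#' @param class_rho Optional within-class equicorrelation of the log2 noise
#'   (default 0 = independent species).
#' @return A list of class `effect_spec`.
#' @export
effect_spec <- function(shifts = numeric(), noise_sigma = 0.5, baseline = NULL,
                        class_rho = 0) {
  stopifnot(is.numeric(shifts), all(is.finite(shifts)), noise_sigma > 0,
            class_rho >= 0, class_rho < 1)
  if (length(shifts) && is.null(names(shifts)))
    stop("shifts must be a named vector (names = species)", call. = FALSE)
  structure(list(shifts = shifts, noise_sigma = noise_sigma,
                 baseline = baseline, class_rho = class_rho),
            class = "effect_spec")
}

#' Effect pattern emulating the observed CLL enrichment/depletion profile
#'
#' Positive log2 shifts on the 18 species-level enrichments seen in
#' treatment-naive CLL plasma (largest on CAR 12:0), negative shifts on the
#' two depleted species (PC 34:1, PC 26:0), zero elsewhere.
#'
#' @param shift Magnitude of the common shift (default 1).
#' @param car12_shift Shift for CAR 12:0 (default 2).
#' @param noise_sigma,class_rho Passed to [effect_spec()].
#' @return An `effect_spec`.
#' @export
cll_effects <- function(shift = 1, car12_shift = 2, noise_sigma = 0.5,
                        class_rho = 0) {
  enriched <- c("PC 36:0", "LPC 18:2", "PC 36:6", "PC 34:4", "PC O-34:3",
                "PC O-38:6", "LPC 17:0", "PC O-36:4;2.0", "LPC 18:0",
                "PC O-34:2", "PC O-36:5", "PC O-36:3", "PC 38:0",
                "PC O-38:5", "PC O-40:1", "SM 18:1;O2/26:0",
                "SM 18:1;O2/22:2;O")
  depleted <- c("PC 34:1", "PC 26:0")
  shifts <- c(stats::setNames(rep(shift, length(enriched)), enriched),
              stats::setNames(rep(-shift, length(depleted)), depleted),
              "CAR 12:0" = car12_shift)
  effect_spec(shifts = shifts, noise_sigma = noise_sigma, class_rho = class_rho)
}

#' Generate a synthetic abundance table
#'
#' Log-normal within-group model: the log2 abundance of species *j* in sample
#' *i* is `baseline_j + shift_j * 1[case] + eps_ij` with
#' `eps ~ Normal(0, noise_sigma^2)` (optionally equicorrelated within
#' headgroup class), exponentiated to a non-negative linear concentration
#' scale. Fully reproducible given the seed.
#'
#' @param design A [cohort_design()].
#' @param effects An [effect_spec()] (default: no shifts).
#' @param seed Integer seed; default taken from the design.
#' @return A list of class `lipid_cohort` with `abundance` (samples x species
#'   numeric matrix, linear scale), `sample_id`, `group` (factor
#'   case/control), `design`, `effects`, `seed`.
#' @examples
#' co <- simulate_cohort(cohort_design(seed = 7), cll_effects())
#' dim(co$abundance)
#' @export
simulate_cohort <- function(design, effects = effect_spec(), seed = design$seed) {
  stopifnot(inherits(design, "cohort_design"), inherits(effects, "effect_spec"))
  panel <- design$panel
  unknown <- setdiff(names(effects$shifts), panel)
  if (length(unknown))
    stop("effects reference species absent from the panel: ",
         paste(unknown, collapse = ", "), call. = FALSE)

  base <- effects$baseline
  if (is.null(base)) {
    pi <- panel_info()
    base <- stats::setNames(pi$baseline_log2, pi$name)
  }
  if (!all(panel %in% names(base)))
    stop("baseline does not cover every panel species", call. = FALSE)
  base <- base[panel]

  shift <- stats::setNames(rep(0, length(panel)), panel)
  shift[names(effects$shifts)] <- effects$shifts

  n <- design$n_case + design$n_control
  grp <- factor(rep(c("case", "control"), c(design$n_case, design$n_control)),
                levels = c("case", "control"))
  set.seed(as.integer(seed))
  eps <- matrix(stats::rnorm(n * length(panel)), n, length(panel))
  if (effects$class_rho > 0) {
    cls <- vapply(panel, function(nm) parse_lipid_name(nm)$lipid_class, character(1))
    for (cl in unique(cls)) {
      idx <- which(cls == cl)
      z <- stats::rnorm(n)
      eps[, idx] <- sqrt(effects$class_rho) * z +
        sqrt(1 - effects$class_rho) * eps[, idx]
    }
  }
  log2x <- sweep(eps * effects$noise_sigma, 2, base, "+")
  log2x <- log2x + outer(as.integer(grp == "case"), shift)
  ab <- 2^log2x
  dimnames(ab) <- list(sprintf("S%02d", seq_len(n)), panel)

  structure(list(abundance = ab,
                 sample_id = rownames(ab),
                 group = grp,
                 design = design, effects = effects, seed = as.integer(seed)),
            class = "lipid_cohort")
}

#' @export
print.lipid_cohort <- function(x, ...) {
  cat(sprintf("<lipid_cohort> %d samples (%d case / %d control) x %d species\n",
              nrow(x$abundance), sum(x$group == "case"),
              sum(x$group == "control"), ncol(x$abundance)))
  invisible(x)
}

#' Write / read a cohort as CSV
#'
#' `write_cohort()` writes `abundance.csv` (first column `sample_id`, one
#' column per species) and `metadata.csv` (`sample_id`, `group`) into `dir`;
#' `read_cohort()` reads the same dialect back and validates it with
#' [validate_cohort()].
#'
#' @param cohort A `lipid_cohort`.
#' @param dir Output directory (created if needed).
#' @return `write_cohort()`: the two file paths, invisibly. `read_cohort()`:
#'   a `lipid_cohort`.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "lipid_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ab <- data.frame(sample_id = cohort$sample_id, cohort$abundance,
                   check.names = FALSE)
  f1 <- file.path(dir, "abundance.csv")
  f2 <- file.path(dir, "metadata.csv")
  utils::write.csv(ab, f1, row.names = FALSE)
  utils::write.csv(data.frame(sample_id = cohort$sample_id,
                              group = as.character(cohort$group)),
                   f2, row.names = FALSE)
  invisible(c(abundance = f1, metadata = f2))
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  validate_cohort(file.path(dir, "abundance.csv"),
                  file.path(dir, "metadata.csv"))
}
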