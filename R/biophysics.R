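#' Load a biophysical annotation rule table
#'
#' The packaged default maps (headgroup class, total-carbon bin,
#' double-bond bin) to five qualitative membrane-biophysics labels:
#' bilayer thickness and lateral diffusion (ordinal, very low..very high),
#' intrinsic curvature (negative/neutral/positive), functional role
#' (membrane component / lipid-mediated signaling) and dominant cellular
#' component (plasma membrane / ER / mitochondrion / other). Rules are plain
#' data with a provenance note per row; bin boundaries are approximate
#' defaults and a custom file with the same columns may be supplied.
#'
#' @param path Path to a rules TSV; `NULL` loads the packaged default.
#' @return A data frame of class `biophys_rules`.
#' @export
biophys_rules <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "biophys_rules.tsv", package = "lipidshift")
  rt <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("lipid_class", "c_min", "c_max", "db_min", "db_max",
            "bilayer_thickness", "lateral_diffusion", "intrinsic_curvature",
            "fn", "cellular_component")
  miss <- setdiff(need, names(rt))
  if (length(miss))
    stop("rules file missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  class(rt) <- c("biophys_rules", "data.frame")
  rt
}

#' Assign biophysical category labels to a lipid
#'
#' Pure table lookup (no membrane simulation): the first rule row whose class
#' and total-carbon / double-bond ranges cover the species supplies all five
#' labels.
#'
#' @param s A `lipid_structure` from [parse_lipid_name()].
#' @param rules A rule table from [biophys_rules()].
#' @return A list with `bilayer_thickness`, `lateral_diffusion`,
#'   `intrinsic_curvature`, `fn` and `cellular_component`.
#' @examples
#' annotate_biophysics(parse_lipid_name("LPC 18:0"))$intrinsic_curvature # "positive"
#' @export
annotate_biophysics <- function(s, rules = biophys_rules()) {
  stopifnot(inherits(s, "lipid_structure"))
  a <- structural_annotation(s)
  hit <- which(rules$lipid_class == s$lipid_class &
               rules$c_min <= a$total_c & a$total_c <= rules$c_max &
               rules$db_min <= a$total_db & a$total_db <= rules$db_max)
  if (length(hit) == 0L)
    stop(sprintf("annotation gap: no biophysics rule covers (%s, total_c=%d, total_db=%d)",
                 s$lipid_class, a$total_c, a$total_db), call. = FALSE)
  r <- rules[hit[1L], ]
  list(bilayer_thickness = r$bilayer_thickness,
       lateral_diffusion = r$lateral_diffusion,
       intrinsic_curvature = r$intrinsic_curvature,
       fn = r$fn,
       cellular_component = r$cellular_component)
}

#' Annotate a set of lipid names
#'
#' Parses every name and derives the full annotation table used by the
#' stratified differential-abundance analysis: classification codes,
#' structural totals, Total FA label, saturation class and the five
#' biophysical labels.
#'
#' @param names Character vector of lipid shorthand names.
#' @param rules Biophysics rule table (default: packaged rules).
#' @return A data frame with one row per input name and columns `raw_name`,
#'   `name` (canonical), `lipid_class`, `category`, `subcategory`, `subclass`,
#'   `total_c`, `total_db`, `total_oh`, `total_fa_label`, `ether_bond`,
#'   `saturation_class`, `bilayer_thickness`, `lateral_diffusion`,
#'   `intrinsic_curvature`, `fn`, `cellular_component`.
#' @examples
#' annotate_lipids(c("CAR 12:0", "PC O-34:2"))
#' @export
annotate_lipids <- function(names, rules = biophys_rules()) {
  stopifnot(is.character(names), length(names) >= 1L)
  rows <- lapply(names, function(nm) {
    s <- parse_lipid_name(nm)
    a <- structural_annotation(s)
    b <- annotate_biophysics(s, rules)
    data.frame(raw_name = nm, name = s$name, lipid_class = s$lipid_class,
               category = s$category, subcategory = s$subcategory_code,
               subclass = s$subclass_code, total_c = a$total_c,
               total_db = a$total_db, total_oh = a$total_oh,
               total_fa_label = a$total_fa_label, ether_bond = a$ether_bond,
               saturation_class = a$saturation_class,
               bilayer_thickness = b$bilayer_thickness,
               lateral_diffusion = b$lateral_diffusion,
               intrinsic_curvature = b$intrinsic_curvature,
               fn = b$fn, cellular_component = b$cellular_component,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
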