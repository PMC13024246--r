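#' Parse a lipid shorthand name
#'
#' Parses LIPID MAPS-style shorthand for the five classes quantified on the
#' panel: acylcarnitines (`CAR`), phosphatidylcholines (`PC`),
#' lysophosphatidylcholines (`LPC`), ether-linked phosphatidylcholines
#' (`PC O-`) and sphingomyelins (`SM`). Species-level names (`"PC 36:0"`,
#' `"SM 34:1;O2"`) are stored as one aggregate chain; molecular-species names
#' with `/` (`"SM 18:1;O2/26:0"`) are resolved per chain. The Unicode minus in
#' `"PC O−"` is accepted and normalized to ASCII, and the dialect oxygen
#' suffix `";2.0"` is normalized to `";O2"` (two oxygen modifiers); both
#' normalizations are recorded in the returned object's `notes` field.
#'
#' @param name A single lipid shorthand name (character).
#' @return An object of class `lipid_structure`: a list with `raw_name`,
#'   `name` (canonical form), `lipid_class`, `category` (`FA`, `GP` or `SP`),
#'   `subcategory_code`, `subclass_code`, `ether_bond`, `chains` (a data frame
#'   with columns `carbons`, `double_bonds`, `oxygens`, `ether_linked`) and
#'   `notes` (character vector of normalizations applied).
#' @examples
#' parse_lipid_name("SM 18:1;O2/26:0")
#' parse_lipid_name("PC O-34:2")
#' @seealso [format.lipid_structure()], [structural_annotation()],
#'   [classify_lipid()]
#' @export
parse_lipid_name <- function(name) {
  if (!is.character(name) || length(name) != 1L || is.na(name) || !nzchar(trimws(name)))
    stop("lipid name must be a single non-empty character string", call. = FALSE)
  raw <- name
  notes <- character()
  x <- trimws(name)
  if (grepl("−", x)) {  # unicode minus
    x <- gsub("−", "-", x)
    notes <- c(notes, "unicode minus normalized to ASCII hyphen")
  }

  m <- regexec("^(CAR|LPC|SM|PC)\\s+(\\S.*)$", x)
  parts <- regmatches(x, m)[[1]]
  if (length(parts) == 0L) {
    cls_tok <- sub("\\s.*$", "", x)
    stop(sprintf("unsupported lipid class prefix in '%s' (token '%s'); supported: CAR, PC, LPC, PC O-, SM",
                 raw, cls_tok), call. = FALSE)
  }
  cls <- parts[2L]
  rest <- parts[3L]
  ether <- FALSE
  if (cls == "PC" && grepl("^O-", rest)) {
    cls <- "PC O-"
    ether <- TRUE
    rest <- sub("^O-", "", rest)
  }

  chain_tokens <- strsplit(rest, "/", fixed = TRUE)[[1]]
  if (length(chain_tokens) < 1L || length(chain_tokens) > 2L)
    stop(sprintf("cannot parse chain specification '%s' in '%s'", rest, raw), call. = FALSE)
  if (cls %in% c("CAR", "LPC") && length(chain_tokens) != 1L)
    stop(sprintf("'%s': %s species carry exactly one chain", raw, cls), call. = FALSE)

  parse_chain <- function(tok) {
    cm <- regexec("^([0-9]+):([0-9]+)(;(.+))?$", tok)
    cp <- regmatches(tok, cm)[[1]]
    if (length(cp) == 0L)
      stop(sprintf("unparseable chain token '%s' in '%s'", tok, raw), call. = FALSE)
    carbons <- as.integer(cp[2L])
    db <- as.integer(cp[3L])
    oxy <- 0L
    mod <- cp[5L]
    if (!is.na(mod) && nzchar(mod)) {
      if (mod == "O") {
        oxy <- 1L
      } else if (grepl("^O[0-9]+$", mod)) {
        oxy <- as.integer(sub("^O", "", mod))
      } else if (grepl("^[0-9]+\\.0$", mod)) {
        # dialect: ";2.0" read as two oxygen modifiers
        oxy <- as.integer(sub("\\.0$", "", mod))
        notes <<- c(notes, sprintf("dialect suffix ';%s' normalized to ';O%d'", mod, oxy))
      } else {
        stop(sprintf("unparseable modifier ';%s' in '%s'", mod, raw), call. = FALSE)
      }
    }
    if (carbons < 1L)
      stop(sprintf("chain '%s' in '%s': carbon count must be >= 1", tok, raw), call. = FALSE)
    if (db > carbons)
      stop(sprintf("chain '%s' in '%s': double bonds exceed carbons", tok, raw), call. = FALSE)
    list(carbons = carbons, double_bonds = db, oxygens = oxy)
  }

  ch <- lapply(chain_tokens, parse_chain)
  chains <- data.frame(
    carbons      = vapply(ch, `[[`, integer(1), "carbons"),
    double_bonds = vapply(ch, `[[`, integer(1), "double_bonds"),
    oxygens      = vapply(ch, `[[`, integer(1), "oxygens"),
    ether_linked = c(ether, rep(FALSE, length(ch) - 1L))
  )

  cl <- .class_codes(cls)
  out <- structure(list(
    raw_name = raw,
    lipid_class = cls,
    category = cl$category,
    subcategory_code = cl$subcategory,
    subclass_code = cl$subclass,
    ether_bond = ether,
    chains = chains,
    notes = notes
  ), class = "lipid_structure")
  out$name <- format(out)
  out
}

# closed-set classification: headgroup class determines the LIPID MAPS codes
.class_codes <- function(cls) {
  switch(cls,
    "CAR"   = list(category = "FA", subcategory = "FA07", subclass = "FA0707"),
    "PC"    = list(category = "GP", subcategory = "GP01", subclass = "GP0101"),
    "PC O-" = list(category = "GP", subcategory = "GP01", subclass = "GP0102"),
    "LPC"   = list(category = "GP", subcategory = "GP01", subclass = "GP0105"),
    "SM"    = list(category = "SP", subcategory = "SP03", subclass = "SP0301"),
    stop(sprintf("unsupported lipid class '%s'", cls), call. = FALSE))
}

#' @rdname parse_lipid_name
#' @param x A `lipid_structure` object.
#' @param ... Ignored.
#' @export
format.lipid_structure <- function(x, ...) {
  fmt_chain <- function(i) {
    ch <- x$chains[i, ]
    lab <- sprintf("%d:%d", ch$carbons, ch$double_bonds)
    if (ch$oxygens == 1L) lab <- paste0(lab, ";O")
    if (ch$oxygens > 1L) lab <- paste0(lab, ";O", ch$oxygens)
    lab
  }
  body <- paste(vapply(seq_len(nrow(x$chains)), fmt_chain, character(1)), collapse = "/")
  if (x$lipid_class == "PC O-") paste0("PC O-", body) else paste(x$lipid_class, body)
}

#' @export
print.lipid_structure <- function(x, ...) {
  cat(sprintf("<lipid_structure> %s  [class %s, %s/%s/%s]\n", x$name,
              x$lipid_class, x$category, x$subcategory_code, x$subclass_code))
  print(x$chains)
  if (length(x$notes)) cat("notes:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}

#' Structural annotation of a parsed lipid
#'
#' Derives the species-level structural totals used for stratified analysis:
#' the Total FA metric (cumulative carbons and double bonds over all
#' esterified chains, plus any oxygen modifiers), hydroxyl/oxygen count,
#' ether-bond flag and saturation class.
#'
#' @param s A `lipid_structure` from [parse_lipid_name()].
#' @return A list with `total_c`, `total_db`, `total_oh`, `ether_bond`,
#'   `saturation_class` and `total_fa_label` (formatted `"C:DB"` with
#'   `";O<k>"` appended when oxygens are present, `k` omitted when 1).
#' @examples
#' structural_annotation(parse_lipid_name("SM 18:1;O2/26:0"))$total_fa_label # "44:1;O2"
#' @export
structural_annotation <- function(s) {
  stopifnot(inherits(s, "lipid_structure"))
  total_c <- sum(s$chains$carbons)
  total_db <- sum(s$chains$double_bonds)
  total_oh <- sum(s$chains$oxygens)
  lab <- sprintf("%d:%d", total_c, total_db)
  if (total_oh == 1L) lab <- paste0(lab, ";O")
  if (total_oh > 1L) lab <- paste0(lab, ";O", total_oh)
  list(total_c = total_c, total_db = total_db, total_oh = total_oh,
       ether_bond = s$ether_bond,
       saturation_class = saturation_class(total_db),
       total_fa_label = lab)
}

#' Saturation class from the total double-bond count
#'
#' @param total_db Integer vector of species-level double-bond totals.
#' @return Character vector: `"saturated"` (0), `"monounsaturated"` (1),
#'   `"diunsaturated"` (2) or `"polyunsaturated"` (3 or more).
#' @export
saturation_class <- function(total_db) {
  stopifnot(is.numeric(total_db), all(total_db >= 0))
  out <- character(length(total_db))
  out[total_db == 0] <- "saturated"
  out[total_db == 1] <- "monounsaturated"
  out[total_db == 2] <- "diunsaturated"
  out[total_db >= 3] <- "polyunsaturated"
  out
}

#' Classify a parsed lipid into LIPID MAPS category codes
#'
#' Deterministic closed-set mapping from headgroup class to category
#' (FA fatty acyls, GP glycerophospholipids, SP sphingolipids), subcategory
#' and subclass codes (e.g. GP0101 diacylglycerophosphocholines, GP0102
#' 1-alkyl,2-acylglycerophosphocholines, SP0301 sphingomyelins).
#'
#' @param s A `lipid_structure`.
#' @return A list with `category`, `subcategory_code`, `subclass_code`.
#' @export
classify_lipid <- function(s) {
  stopifnot(inherits(s, "lipid_structure"))
  list(category = s$category, subcategory_code = s$subcategory_code,
       subclass_code = s$subclass_code)
}
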