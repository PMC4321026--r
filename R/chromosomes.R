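#' hetseg: heterologous segregation and secondary nondisjunction in fly meiosis
#'
#' Tools to model meiosis I segregation of aberrant chromosome configurations in
#' *Drosophila melanogaster* females (compound chromosomes, balancer
#' heterozygotes, XXY females), estimate viability-corrected segregation rates
#' and map distances from progeny counts, and verify every estimator by
#' parameter recovery against a seeded forward simulator.
#'
#' @section Main entry points:
#' * [karyotype_preset()], [cross_preset()] -- the built-in genotypes.
#' * [gamete_distribution()] -- exact ovum class probabilities.
#' * [genetic_hs_rate()], [cytological_rates()], [map_distance()] -- estimators.
#' * [correction_factor()] -- viability-derived count corrections.
#' * [simulate_cross()], [simulate_oocytes()], [recovery_report()] -- simulator.
#' * [load_counts()], [fixture_path()] -- delimited-text IO and fixtures.
#' * [hs_cli()] -- command-line interface.
#'
#' @name hetseg-package
#' @keywords internal
"_PACKAGE"

# chromosome elements tracked by the dose bookkeeping
HS_ELEMENTS <- c("X", "Y", "2L", "2R", "3L", "3R", "4")

HS_REARRANGEMENTS <- c("normal", "compound", "inversion", "balancer",
                       "Y_derived", "empty")

#' Construct a chromosome copy
#'
#' A chromosome copy is one physical DNA molecule a female can transmit: a
#' normal homolog, a compound chromosome (carrying two doses of an arm or a
#' whole element), a balancer, a free or derived Y, or the empty placeholder
#' used in genotype notation (e.g. `C(4)RM / 0`).
#'
#' @param id unique identifier within a karyotype.
#' @param elements named integer vector of element doses, names among
#'   `X, Y, 2L, 2R, 3L, 3R, 4`. The empty placeholder carries no elements.
#' @param rearrangement one of `"normal"`, `"compound"`, `"inversion"`,
#'   `"balancer"`, `"Y_derived"`, `"empty"`.
#' @param markers character vector of visible marker labels carried.
#' @param exchange_competent can this copy take part in crossing-over?
#'   Balancers block exchange entirely; inversions are modelled as competent,
#'   with the suppression expressed through the nonexchange probability.
#' @param label display/class label; copies with equal labels are treated as
#'   interchangeable when gamete classes are formed (e.g. the two normal 4s).
#' @return an object of class `chromosome_copy`.
#' @examples
#' chromosome_copy("C1", c(X = 2), "compound", markers = c("y", "v"))
#' @export
chromosome_copy <- function(id, elements = integer(), rearrangement = "normal",
                            markers = character(),
                            exchange_competent = rearrangement == "normal",
                            label = id) {
  stopifnot(is.character(id), length(id) == 1L)
  rearrangement <- match.arg(rearrangement, HS_REARRANGEMENTS)
  elements <- elements[elements != 0]
  if (length(elements)) {
    if (is.null(names(elements)) || !all(names(elements) %in% HS_ELEMENTS))
      stop("chromosome elements must be named among: ",
           paste(HS_ELEMENTS, collapse = ", "))
    if (any(elements < 0)) stop("element doses must be >= 0")
    storage.mode(elements) <- "integer"
  } else {
    elements <- integer()
  }
  if (rearrangement == "empty" && length(elements))
    stop("an 'empty' placeholder must carry zero dose of every element")
  if (rearrangement == "compound" && !any(elements >= 2L))
    stop("a compound must carry dose 2 of at least one element")
  structure(
    list(id = id, elements = elements, rearrangement = rearrangement,
         markers = as.character(markers),
         exchange_competent = isTRUE(exchange_competent),
         label = label),
    class = "chromosome_copy"
  )
}

#' @export
print.chromosome_copy <- function(x, ...) {
  dose <- if (length(x$elements))
    paste(sprintf("%s:%d", names(x$elements), x$elements), collapse = " ")
  else "(empty)"
  cat(sprintf("<chromosome_copy %s [%s] %s%s>\n", x$id, x$rearrangement, dose,
              if (length(x$markers))
                paste0(" markers=", paste(x$markers, collapse = ","))
              else ""))
  invisible(x)
}

#' Construct a karyotype
#'
#' @param copies list of [chromosome_copy()] objects with unique ids.
#' @param label free-text genotype label.
#' @return an object of class `karyotype`.
#' @examples
#' karyotype(list(
#'   chromosome_copy("X1", c(X = 1), markers = c("y", "w")),
#'   chromosome_copy("X2", c(X = 1), markers = c("y", "w")),
#'   chromosome_copy("yY", c(Y = 1), "Y_derived")
#' ), label = "y w / y w / y+Y")
#' @export
karyotype <- function(copies, label = "") {
  stopifnot(is.list(copies))
  copies <- copies[vapply(copies, function(cp)
    !identical(cp$rearrangement, "empty"), logical(1))]
  if (!all(vapply(copies, inherits, logical(1), "chromosome_copy")))
    stop("all copies must be chromosome_copy objects")
  ids <- vapply(copies, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("copy ids must be unique within a karyotype")
  names(copies) <- ids
  structure(list(copies = copies, label = label), class = "karyotype")
}

#' Total element dose of a karyotype or copy set
#'
#' @param x a `karyotype`, or a list of `chromosome_copy`.
#' @return named integer vector over the seven tracked elements.
#' @export
element_dose <- function(x) {
  copies <- if (inherits(x, "karyotype")) x$copies else x
  dose <- stats::setNames(integer(length(HS_ELEMENTS)), HS_ELEMENTS)
  for (cp in copies) {
    el <- cp$elements
    if (length(el)) dose[names(el)] <- dose[names(el)] + el
  }
  dose
}

#' @export
print.karyotype <- function(x, ...) {
  cat(sprintf("<karyotype%s: %d copies>\n",
              if (nzchar(x$label)) paste0(" ", x$label) else "", length(x$copies)))
  for (cp in x$copies) print(cp)
  dose <- element_dose(x)
  dose <- dose[dose > 0]
  cat("  total dose:", paste(sprintf("%s:%d", names(dose), dose), collapse = " "), "\n")
  invisible(x)
}

## ---- copy catalog and karyotype presets ------------------------------------

# Internal catalog of the chromosome copies occurring in the studied genotypes.
# Maternal copies carry the stock markers; paternal (tester) copies are
# suffixed "p" so ovum and sperm contributions stay distinguishable.
copy_catalog <- function() {
  cc <- list(
    chromosome_copy("X.ywf", c(X = 1), "normal", c("y", "w", "f")),
    chromosome_copy("X.yw",  c(X = 1), "normal", c("y", "w")),
    chromosome_copy("X",     c(X = 1), "normal"),
    chromosome_copy("FM7",   c(X = 1), "balancer", c("y", "w", "B"),
                    exchange_competent = FALSE),
    chromosome_copy("In1",   c(X = 1), "inversion", c("y", "v", "f"),
                    exchange_competent = TRUE),
    chromosome_copy("Y",     c(Y = 1), "normal"),
    chromosome_copy("yY",    c(Y = 1), "Y_derived", "y+"),
    chromosome_copy("C1",    c(X = 2), "compound", c("y", "v")),
    chromosome_copy("C4",    c(`4` = 2), "compound", c("ci", "eyR")),
    chromosome_copy("C2EN",  c(`2L` = 2, `2R` = 2), "compound", c("bw", "sp")),
    chromosome_copy("C2L",   c(`2L` = 2), "compound", "b"),
    chromosome_copy("C2R",   c(`2R` = 2), "compound", "px"),
    chromosome_copy("4a",    c(`4` = 1), "normal", label = "4"),
    chromosome_copy("4b",    c(`4` = 1), "normal", label = "4"),
    # paternal copies
    chromosome_copy("Xp",    c(X = 1), "normal", c("y", "w", "f"), label = "Xp"),
    chromosome_copy("Yp",    c(Y = 1), "Y_derived", "y+", label = "Yp"),
    chromosome_copy("4p",    c(`4` = 1), "normal", label = "4p"),
    chromosome_copy("C4p",   c(`4` = 2), "compound", c("ci", "eyR"), label = "C4p"),
    # attached X-Y(short) tester chromosome: one X dose plus Y material
    chromosome_copy("C1YSp", c(X = 1, Y = 1), "Y_derived", c("v", "f", "B"),
                    label = "C1YSp"),
    chromosome_copy("C2Lp",  c(`2L` = 2), "compound", label = "C2Lp"),
    chromosome_copy("C2Rp",  c(`2R` = 2), "compound", label = "C2Rp")
  )
  names(cc) <- vapply(cc, `[[`, character(1), "id")
  cc
}

HS_PRESETS <- c("C1_mono", "C2EN_mono", "C4_mono", "In1_C4", "FM7_C4",
                "XXY_yw", "FM7_XXY", "In1_XXY", "C1C4", "C2L_C2R")

#' List the built-in genotype presets
#'
#' One preset per genotype row of the packaged count tables. Monovalent
#' compound genotypes: `C1_mono`, `C2EN_mono`, `C4_mono`, `In1_C4`, `FM7_C4`.
#' Multiple-partner genotypes: `XXY_yw`, `FM7_XXY`, `In1_XXY`, `C1C4`,
#' `C2L_C2R`.
#'
#' @return character vector of preset names.
#' @export
list_presets <- function() HS_PRESETS

#' Built-in female karyotypes
#'
#' @param name one of [list_presets()].
#' @return a [karyotype()].
#' @examples
#' element_dose(karyotype_preset("XXY_yw"))  # X dose 2, Y dose 1
#' @export
karyotype_preset <- function(name) {
  name <- match.arg(name, HS_PRESETS)
  cc <- copy_catalog()
  pick <- function(ids, label) {
    copies <- cc[ids]
    # duplicate ids (two copies of the same X) get distinct ids, same label
    out <- list(); seen <- character()
    for (cp in copies) {
      if (cp$id %in% seen) {
        cp$id <- paste0(cp$id, ".2")
      }
      seen <- c(seen, cp$id)
      out <- c(out, list(cp))
    }
    karyotype(out, label = label)
  }
  switch(name,
    C1_mono   = pick(c("C1", "4a", "4b"), "C(1)RM, y v / 0"),
    C2EN_mono = pick(c("X", "X", "C2EN", "4a", "4b"), "C(2)EN, bw sp / 0"),
    C4_mono   = pick(c("X.ywf", "X.ywf", "C4"), "y w f; C(4)RM / 0"),
    In1_C4    = pick(c("X.ywf", "In1", "C4"), "y w f / In(1)dl-49; C(4)RM / 0"),
    FM7_C4    = pick(c("X.ywf", "FM7", "C4"), "y w f / FM7; C(4)RM / 0"),
    XXY_yw    = pick(c("X.yw", "X.yw", "yY", "4a", "4b"), "y w / y w / y+Y"),
    FM7_XXY   = pick(c("FM7", "X.yw", "yY", "4a", "4b"), "FM7, y w B / y w / y+Y"),
    In1_XXY   = pick(c("In1", "X.ywf", "Y", "4a", "4b"),
                     "In(1)dl-49, y v f / y w f / Y"),
    C1C4      = pick(c("C1", "C4"), "C(1)RM, y v / 0; C(4)RM, ci eyR / 0"),
    C2L_C2R   = pick(c("X", "X", "C2L", "C2R", "4a", "4b"),
                     "C(2L)RM-P1, b / 0; C(2R)RM-P4, px / 0")
  )
}

#' Load a karyotype from a JSON-compatible configuration
#'
#' The configuration is either `list(preset = "<name>")` or a list with
#' `label` and `copies`, each copy a list with fields `id`, `elements`
#' (named doses), `rearrangement`, `markers`, `exchange_competent`, `label`.
#'
#' @param config a list (already parsed) or a path to a JSON file.
#' @return a [karyotype()].
#' @export
karyotype_from_config <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = FALSE)
  if (!is.null(config$preset)) return(karyotype_preset(config$preset))
  if (is.null(config$copies)) stop("karyotype config needs 'preset' or 'copies'")
  copies <- lapply(config$copies, function(cp) {
    el <- unlist(cp$elements %||% list())
    chromosome_copy(cp$id,
                    elements = stats::setNames(as.integer(el), names(el)),
                    rearrangement = cp$rearrangement %||% "normal",
                    markers = unlist(cp$markers %||% character()),
                    exchange_competent = cp$exchange_competent %||%
                      ((cp$rearrangement %||% "normal") == "normal"),
                    label = cp$label %||% cp$id)
  })
  karyotype(copies, label = config$label %||% "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
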