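## Delimited-text readers/writers and the packaged count-table fixtures.
## Dialect: tab-separated, UTF-8, mandatory header row, "." decimal separator.
## Fixtures store raw counts and footnote subsets only; every percentage is
## always recomputed.

HS_SCHEMAS <- list(
  oocyte = c("stage", "single_mass", "one_plus_out", "compound_out",
             "hs_config", "other_config"),
  progeny = c("normal", "hs_exceptional", "other", "recombinant",
              "paternal_ndj")
)

#' Read a validated count table
#'
#' Reads a tab-separated count table in one of the two fixed schemas and
#' validates every row; malformed rows are reported with their line number
#' and the offending field. Extra metadata columns (`genotype`, `decimals`)
#' are allowed and preserved.
#'
#' Oocyte schema: `stage, single_mass, one_plus_out, compound_out, hs_config,
#' other_config`. Progeny schema: `normal, hs_exceptional, other, recombinant,
#' paternal_ndj`.
#'
#' @param path file path.
#' @param schema `"oocyte"` or `"progeny"`.
#' @return data frame with one row per genotype/stage; convert single rows
#'   with [as_oocyte_config_counts()] / [as_progeny_count_table()].
#' @export
load_counts <- function(path, schema = c("oocyte", "progeny")) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop("file not found: ", path)
  need <- HS_SCHEMAS[[schema]]
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("missing column(s) in ", basename(path), ": ",
         paste(missing, collapse = ", "))
  for (i in seq_len(nrow(df))) {
    line <- i + 1L  # header is line 1
    for (col in need) {
      v <- df[[col]][i]
      if (col == "stage") {
        if (!v %in% c("prometaphase_2d", "metaphase_4d"))
          stop(sprintf("line %d: invalid stage '%s'", line, v))
        next
      }
      if (is.na(v) || !is.numeric(v) || v < 0 || v != round(v))
        stop(sprintf("line %d: field '%s' must be a nonnegative integer count",
                     line, col))
    }
    if (schema == "oocyte") {
      if (df$compound_out[i] > df$one_plus_out[i])
        stop(sprintf("line %d: field 'compound_out' exceeds one_plus_out", line))
      if (df$hs_config[i] > df$single_mass[i] + df$one_plus_out[i])
        stop(sprintf("line %d: field 'hs_config' exceeds scored oocytes", line))
    } else {
      if (df$recombinant[i] + df$paternal_ndj[i] > df$other[i])
        stop(sprintf(
          "line %d: field 'recombinant'+'paternal_ndj' exceeds 'other'", line))
    }
  }
  df
}

#' Write a count table
#'
#' Tab-separated, UTF-8, header row, no quoting; [load_counts()] output
#' round-trips byte-identically.
#'
#' @param df data frame in one of the count schemas.
#' @param path output file path (or `""` for standard output).
#' @return `path`, invisibly.
#' @export
write_counts <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     eol = "\n", fileEncoding = "")
  invisible(path)
}

#' Convert a count-table row to a typed object
#'
#' @param row single-row data frame in the matching schema.
#' @return an [oocyte_config_counts()] or [progeny_count_table()].
#' @export
as_oocyte_config_counts <- function(row) {
  stopifnot(nrow(row) == 1L)
  oocyte_config_counts(row$stage, row$single_mass, row$one_plus_out,
                       row$compound_out, row$hs_config, row$other_config)
}

#' @rdname as_oocyte_config_counts
#' @export
as_progeny_count_table <- function(row) {
  stopifnot(nrow(row) == 1L)
  progeny_count_table(row$normal, row$hs_exceptional, row$other,
                      row$recombinant, row$paternal_ndj)
}

#' Path to a packaged fixture
#'
#' Available fixtures: `table1_cytology`, `table1_progeny`,
#' `table2_cytology`, `table2_progeny`, `table2_in1_classes` -- the raw
#' oocyte and progeny counts of the published tables (marginals and
#' footnote-level class breakdowns; no percentages are stored).
#'
#' @param name fixture name without extension.
#' @return file path inside the installed package.
#' @export
fixture_path <- function(name) {
  p <- system.file("extdata", paste0(name, ".tsv"), package = "hetseg")
  if (!nzchar(p)) stop("unknown fixture: ", name)
  p
}

#' Load the packaged count tables
#'
#' `load_table1()`: monovalent-compound genotypes (cytology at both stages +
#' progeny counts with per-row reporting precision). `load_table2()`:
#' multiple-partner genotypes (metaphase orientation counts + progeny
#' counts). `load_in1_class_breakdown()`: the footnote-level phenotype-class
#' breakdown of the inversion-heterozygote XXY cross, whose marginals equal
#' the main table's counts.
#'
#' @return `load_table1`/`load_table2`: list with `cytology` and `progeny`
#'   data frames; `load_in1_class_breakdown`: data frame with `class`,
#'   `count`, `partition`.
#' @export
load_table1 <- function() {
  list(cytology = load_counts(fixture_path("table1_cytology"), "oocyte"),
       progeny = load_counts(fixture_path("table1_progeny"), "progeny"))
}

#' @rdname load_table1
#' @export
load_table2 <- function() {
  list(cytology = load_counts(fixture_path("table2_cytology"), "oocyte"),
       progeny = load_counts(fixture_path("table2_progeny"), "progeny"))
}

#' @rdname load_table1
#' @export
load_in1_class_breakdown <- function() {
  df <- utils::read.delim(fixture_path("table2_in1_classes"), sep = "\t",
                          header = TRUE, stringsAsFactors = FALSE)
  stopifnot(all(c("class", "count", "partition") %in% names(df)))
  df
}
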