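# Animal records and cohort tables.

.genotype_levels <- c("mutant", "wildtype")
.sex_levels <- c("M", "F")
.age_levels <- c("premanifest", "manifest")
.strain_levels <- c("B6", "FVB")

#' Construct a validated cohort table
#'
#' A cohort is a data frame of animal records: one row per animal with its
#' identity, genotype (knock-in mutant vs wild-type littermate), sex, age
#' group (premanifest, 2-3 months; manifest, 9-12 months), background strain
#' and body weight in grams. All grouping and weight normalization downstream
#' is anchored on this table.
#'
#' @param df data frame with columns `animal_id`, `genotype`, `sex`,
#'   `age_group`, `strain`, `weight_g`.
#' @return the validated data frame with class `cohort` prepended.
#' @examples
#' cohort(data.frame(animal_id = c("a", "b"),
#'                   genotype = c("mutant", "wildtype"),
#'                   sex = "M", age_group = "manifest", strain = "B6",
#'                   weight_g = c(31.5, 42)))
#' @export
cohort <- function(df) {
  required <- c("animal_id", "genotype", "sex", "age_group", "strain",
                "weight_g")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("cohort table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df$animal_id <- as.character(df$animal_id)
  if (anyDuplicated(df$animal_id)) {
    stop("duplicated animal_id in cohort: ",
         paste(unique(df$animal_id[duplicated(df$animal_id)]),
               collapse = ", "), call. = FALSE)
  }
  check_enum <- function(x, levels, name) {
    bad <- setdiff(unique(as.character(x)), levels)
    if (length(bad)) {
      stop(sprintf("unknown %s value(s): %s (expected one of %s)", name,
                   paste(bad, collapse = ", "),
                   paste(levels, collapse = ", ")), call. = FALSE)
    }
    factor(as.character(x), levels = levels)
  }
  df$genotype <- check_enum(df$genotype, .genotype_levels, "genotype")
  df$sex <- check_enum(df$sex, .sex_levels, "sex")
  df$age_group <- check_enum(df$age_group, .age_levels, "age_group")
  df$strain <- check_enum(df$strain, .strain_levels, "strain")
  if (!is.numeric(df$weight_g) || any(!is.finite(df$weight_g)) ||
      any(df$weight_g <= 0)) {
    stop("weight_g must be finite and positive for every animal",
         call. = FALSE)
  }
  class(df) <- c("cohort", "data.frame")
  df
}

#' Read a cohort table from CSV
#'
#' @param path CSV file with the columns documented in [cohort()].
#' @return a validated [cohort()] data frame.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  cohort(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Write a cohort table to CSV
#'
#' @param x a [cohort()] data frame.
#' @param path output CSV path.
#' @export
write_cohort <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d animals (%d mutant / %d wildtype)\n",
              nrow(x), sum(x$genotype == "mutant"),
              sum(x$genotype == "wildtype")))
  print(as.data.frame(utils::head(x, 10)))
  if (nrow(x) > 10) cat(sprintf("... and %d more rows\n", nrow(x) - 10))
  invisible(x)
}
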