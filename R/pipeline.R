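load_config_paths <- function(ra_path = NULL, lexicon_path = NULL,
                              allow_list_path = NULL) {
  for (p in c(ra_path, lexicon_path, allow_list_path)) {
    if (!is.null(p) && !file.exists(p)) {
      stop("configuration file not found: ", p, call. = FALSE)
    }
  }
  list(ra_table = read_reference_amounts(ra_path),
       lexicon = read_lexicon(lexicon_path),
       allow_list = read_allow_list(allow_list_path))
}

npm_log <- function(verbose, ...) {
  if (verbose) message(sprintf(...))
}

#' Run the cleaning and classification pipeline
#'
#' Orchestrates the full per-product pipeline: read (or take) a product
#' table, clean it (deduplicate, Atwater plausibility, missing-data
#' exclusion), resolve added-ingredient flags and classify every
#' remaining product against the marketing-to-children thresholds.
#' Every input product ends up in exactly one of the classification
#' output or the exclusion log. Configuration is validated before any
#' processing; identical inputs and configuration give identical
#' outputs.
#'
#' @param input Product tibble or path to a product CSV.
#' @param output_dir Optional directory; when given, writes
#'   `classified.csv` and `exclusions.csv`.
#' @param ra_path,lexicon_path,allow_list_path Optional configuration
#'   file paths overriding the packaged defaults.
#' @param params [npm_params()] or a list of overrides.
#' @param verbose Log stage counts to standard error.
#' @return A list with `classifications`, `exclusions`, `flags`,
#'   `stage_counts` and `row_errors` (invalid input rows skipped on
#'   read).
#' @export
run_classify <- function(input, output_dir = NULL, ra_path = NULL,
                         lexicon_path = NULL, allow_list_path = NULL,
                         params = npm_params(), verbose = FALSE) {
  params <- as_npm_params(params)
  cfg <- load_config_paths(ra_path, lexicon_path, allow_list_path)
  products <- if (is.character(input)) read_products(input) else
    validate_products(input)
  row_errors <- attr(products, "row_errors")
  npm_log(verbose, "input products: %d (plus %d invalid rows skipped)",
          nrow(products), nrow(row_errors))
  cleaned <- clean_products(products, params)
  npm_log(verbose, "after cleaning: %d kept, %d excluded (%s)",
          nrow(cleaned$products), nrow(cleaned$exclusions),
          paste(names(table(cleaned$exclusions$reason)),
                table(cleaned$exclusions$reason), sep = "=", collapse = ", "))
  flags <- resolve_flags(cleaned$products, cfg$lexicon, cfg$allow_list)
  classifications <- classify_products(cleaned$products, cfg$ra_table,
                                       cfg$lexicon, cfg$allow_list, params)
  npm_log(verbose, "classified: %d (%d restricted, %d permitted)",
          nrow(classifications),
          sum(classifications$status == "restricted"),
          sum(classifications$status == "permitted"))
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    write_classifications(classifications,
                          file.path(output_dir, "classified.csv"))
    write_exclusions(cleaned$exclusions,
                     file.path(output_dir, "exclusions.csv"))
  }
  list(classifications = classifications, exclusions = cleaned$exclusions,
       flags = flags, stage_counts = cleaned$stage_counts,
       row_errors = row_errors)
}

#' Run the brand and study summaries
#'
#' Aggregates a classification table (from [run_classify()] or a
#' `classified.csv` written by it) into per-brand summaries and the
#' study-level brand tallies.
#'
#' @param classifications Classification tibble or path to a
#'   classification CSV.
#' @param output_dir Optional directory; when given, writes
#'   `brand_summaries.csv` (percentages rounded to one decimal) and
#'   `study_summary.json`.
#' @param params [npm_params()].
#' @param verbose Print the study table.
#' @return A list with `brand_summaries` (full precision) and `study`.
#' @export
run_summarize <- function(classifications, output_dir = NULL,
                          params = npm_params(), verbose = FALSE) {
  params <- as_npm_params(params)
  if (is.character(classifications)) {
    if (!file.exists(classifications)) {
      stop("classification file not found: ", classifications, call. = FALSE)
    }
    classifications <- readr::read_csv(classifications,
                                       show_col_types = FALSE, progress = FALSE)
  }
  brand_summaries <- summarize_brands(classifications)
  study <- summarize_study(brand_summaries, params)
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    write_brand_summaries(brand_summaries,
                          file.path(output_dir, "brand_summaries.csv"))
    write_study_summary(study, file.path(output_dir, "study_summary.json"),
                        quiet = !verbose)
  } else if (verbose) {
    write_study_summary(study, tempfile(fileext = ".json"), quiet = FALSE)
  }
  list(brand_summaries = brand_summaries, study = study)
}

#' Simulate a synthetic dataset on disk
#'
#' Generates a synthetic product table with ground truth, optionally
#' plants cleaning artifacts, and writes `products.csv`,
#' `ground_truth.csv` and `injection_manifest.csv` in the formats the
#' rest of the pipeline reads. Repeatable for a fixed seed.
#'
#' @param output_dir Directory to write into (created if needed).
#' @param n_per_category Products per category profile.
#' @param seed Integer seed.
#' @param profiles List of [category_profile()] objects.
#' @param dup_rate,missing_rate,atwater_corrupt_rate Artifact rates for
#'   [inject_artifacts()].
#' @return Invisibly, the list from [generate_products()] plus the
#'   injection `manifest` and the modified `products`.
#' @export
run_simulate <- function(output_dir, n_per_category = 40, seed = 1,
                         profiles = default_profiles(), dup_rate = 0,
                         missing_rate = 0, atwater_corrupt_rate = 0) {
  gen <- generate_products(profiles, n_per_category, seed)
  inj <- inject_artifacts(gen$products, dup_rate, missing_rate,
                          atwater_corrupt_rate, seed = seed + 1)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  write_products(inj$products, file.path(output_dir, "products.csv"))
  readr::write_csv(gen$ground_truth, file.path(output_dir, "ground_truth.csv"),
                   na = "")
  readr::write_csv(inj$manifest,
                   file.path(output_dir, "injection_manifest.csv"), na = "")
  invisible(list(products = inj$products, ground_truth = gen$ground_truth,
                 manifest = inj$manifest))
}
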