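#' Read an ingredient lexicon
#'
#' The lexicon drives the ingredient-based exemption gate: only products
#' containing added sodium, free sugars or added fat are evaluated
#' against the corresponding threshold. It holds three term lists
#' (sodium, free-sugar and added-fat sources) plus negation exceptions —
#' phrases such as "unsalted" or "no sugar added" inside which a term
#' never counts. Free-sugar terms target added and free sources only:
#' naturally occurring lactose in plain dairy or intrinsic fruit sugars
#' do not trigger the gate.
#'
#' @param path YAML path; default is the lexicon shipped with the
#'   package, seeded from the example ingredient sources in Health
#'   Canada's proposal and user-extensible.
#' @return A list of class `npm_lexicon` with `sodium_terms`,
#'   `free_sugar_terms`, `added_fat_terms`, `negation_exceptions`.
#' @export
read_lexicon <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "lexicon.yaml", package = "m2knpm",
                        mustWork = TRUE)
  }
  if (!file.exists(path)) stop("lexicon file not found: ", path, call. = FALSE)
  lex <- yaml::read_yaml(path)
  required <- c("sodium_terms", "free_sugar_terms", "added_fat_terms")
  missing_keys <- setdiff(required, names(lex))
  if (length(missing_keys)) {
    stop("lexicon is missing term lists: ", paste(missing_keys, collapse = ", "),
         call. = FALSE)
  }
  lex$negation_exceptions <- lex$negation_exceptions %||% character()
  for (k in c(required, "negation_exceptions")) {
    lex[[k]] <- as.character(lex[[k]])
    if (any(!nzchar(trimws(lex[[k]])))) {
      stop("lexicon contains an empty term in ", k, call. = FALSE)
    }
  }
  structure(lex, class = "npm_lexicon")
}

#' @rdname read_lexicon
#' @export
default_lexicon <- function() read_lexicon()

#' Read an exemption allow-list
#'
#' Name patterns for items (typically restaurant items, which lack
#' ingredient lists) that can reasonably be assumed to contain no added
#' sodium, free sugars or added fat — e.g. bottled water or raw apple
#' slices — and are therefore exempt from all thresholds.
#'
#' @param path YAML path with a `patterns` list; default is the shipped
#'   allow-list.
#' @return Character vector of patterns, matched case-insensitively as
#'   substrings of the product name.
#' @export
read_allow_list <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "allow_list.yaml", package = "m2knpm",
                        mustWork = TRUE)
  }
  if (!file.exists(path)) stop("allow-list file not found: ", path, call. = FALSE)
  al <- yaml::read_yaml(path)
  if (is.null(al$patterns)) stop("allow-list must have a 'patterns' key", call. = FALSE)
  as.character(al$patterns)
}

#' @rdname read_allow_list
#' @export
default_allow_list <- function() read_allow_list()

term_regex <- function(terms) {
  esc <- gsub("([^[:alnum:][:space:]])", "\\\\\\1", terms)
  paste0("\\b(", paste(esc, collapse = "|"), ")\\b")
}

#' Detect lexicon terms in ingredient text
#'
#' Scans an ingredient list for any of the given terms, case-insensitive
#' and word-boundary aware, phrase by phrase (phrases are the
#' comma/semicolon/parenthesis-separated segments of the list). A term
#' occurrence is suppressed when it falls inside a negation-exception
#' phrase ("unsalted", "no sugar added") or is preceded by "no" or
#' "without" within the same phrase.
#'
#' @param text Character vector of ingredient lists (`NA` or empty =
#'   unknown).
#' @param terms Character vector of terms.
#' @param exceptions Character vector of exception phrases.
#' @return Character vector: `"present"`, `"absent"` or `"unknown"`.
#' @examples
#' detect_term("water, honey, citric acid", c("honey", "sugar"))   # present
#' detect_term("milk, unsalted butter", "salt")                     # absent
#' @export
detect_term <- function(text, terms, exceptions = character()) {
  stopifnot(is.character(terms), length(terms) > 0)
  out <- rep("unknown", length(text))
  known <- !is.na(text) & nzchar(trimws(text))
  if (!any(known)) return(out)
  term_re <- stringr::regex(term_regex(terms), ignore_case = TRUE)
  exc_re <- if (length(exceptions)) {
    stringr::regex(term_regex(exceptions), ignore_case = TRUE)
  }
  neg_re <- stringr::regex("\\b(no|without)\\b.*", ignore_case = TRUE)
  hit_one <- function(txt) {
    phrases <- stringr::str_split(txt, "[,;()\\.]")[[1]]
    if (!is.null(exc_re)) phrases <- stringr::str_remove_all(phrases, exc_re)
    phrases <- stringr::str_remove_all(phrases, neg_re)
    any(stringr::str_detect(phrases, term_re))
  }
  out[known] <- ifelse(vapply(text[known], hit_one, logical(1)),
                       "present", "absent")
  out
}

#' Resolve added-ingredient flags for a product table
#'
#' Determines, per product, the tri-state presence of added sodium, free
#' sugars and added fat — the gate deciding whether each threshold
#' applies. Precedence, per flag:
#' \enumerate{
#'   \item an explicit flag column (`flag_sodium`, `flag_sugars`,
#'     `flag_fat` with values `present`/`absent`) always wins
#'     (provenance `explicit`);
#'   \item otherwise lexicon detection on `ingredients_text`
#'     (provenance `lexicon`);
#'   \item records without ingredient text (typical for restaurant
#'     items) match the allow-list of plainly unprocessed items →
#'     all three flags `absent` (provenance `allow_list`);
#'   \item everything else defaults conservatively to `present`
#'     (provenance `default`): without an ingredient list a processed
#'     item cannot reasonably be assumed free of added ingredients.
#' }
#'
#' @param products Product tibble.
#' @param lexicon [read_lexicon()] object.
#' @param allow_list Character vector of name patterns.
#' @return A tibble with `product_id`, the three flags (`added_sodium`,
#'   `free_sugars`, `added_fat`, each `present`/`absent`) and a
#'   provenance column per flag.
#' @export
resolve_flags <- function(products, lexicon = default_lexicon(),
                          allow_list = default_allow_list()) {
  stopifnot(inherits(lexicon, "npm_lexicon"))
  n <- nrow(products)
  text <- products$ingredients_text
  exc <- lexicon$negation_exceptions
  det <- list(
    added_sodium = detect_term(text, lexicon$sodium_terms, exc),
    free_sugars = detect_term(text, lexicon$free_sugar_terms, exc),
    added_fat = detect_term(text, lexicon$added_fat_terms, exc))

  allowed <- rep(FALSE, n)
  if (length(allow_list)) {
    allow_re <- stringr::regex(
      paste(gsub("([^[:alnum:][:space:]])", "\\\\\\1", allow_list),
            collapse = "|"), ignore_case = TRUE)
    allowed <- stringr::str_detect(products$name, allow_re)
  }

  explicit <- list(added_sodium = products$flag_sodium,
                   free_sugars = products$flag_sugars,
                   added_fat = products$flag_fat)
  out <- tibble::tibble(product_id = products$product_id)
  for (nm in names(det)) {
    ex <- explicit[[nm]]
    if (!all(is.na(ex) | ex %in% c("present", "absent"))) {
      stop("explicit flags must be 'present', 'absent' or empty", call. = FALSE)
    }
    val <- det[[nm]]
    src <- ifelse(val == "unknown", NA_character_, "lexicon")
    unknown <- val == "unknown"
    val[unknown & allowed] <- "absent"
    src[unknown & allowed] <- "allow_list"
    val[unknown & !allowed] <- "present"
    src[unknown & !allowed] <- "default"
    has_ex <- !is.na(ex)
    val[has_ex] <- ex[has_ex]
    src[has_ex] <- "explicit"
    out[[nm]] <- val
    out[[paste0(nm, "_src")]] <- src
  }
  out
}
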