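#' Search-term vocabulary behind the six query categories
#'
#' Loads the vendored synthetic vocabulary of 111 search terms grouped
#' into the six query categories that define the search-rate streams
#' (suicide seeking, suicide prevention, suicide neutral, mood/anxiety,
#' psychosis, stressor/trauma). The list is a synthetic stand-in built
#' around published example terms per category ("commit suicide",
#' "suicide hotline", "suicides", "depressed", "delusion", "social
#' isolation") and documents the vocabulary structure; it is not a
#' registry of the exact operational query set.
#'
#' @param path CSV with columns `category`, `term` (default: the vendored
#'   file).
#' @return data frame with columns `category` (factor over the six
#'   categories) and `term`.
#' @export
load_search_terms <- function(path = system.file("extdata",
                                                 "search_terms_synthetic.csv",
                                                 package = "lagcast")) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("category", "term") %in% names(df)))
    stop("term list must have columns category and term")
  bad <- setdiff(unique(df$category), search_categories())
  if (length(bad)) stop("unknown term categories: ", paste(bad, collapse = ", "))
  df$category <- factor(df$category, levels = search_categories())
  df
}
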