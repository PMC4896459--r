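#' Score a raw ECDI response, applying reverse coding
#'
#' ECDI items are answered yes/no by the caregiver. After coding, a score of
#' 1 always means the favorable outcome: for ordinary items "yes" scores 1,
#' while for reverse-coded items ("too sick to play", "kicks, bites, or
#' hits", "easily distracted") "yes" indicates a problem and scores 0.
#'
#' @param response vector of raw responses: "yes"/"no" (or TRUE/FALSE, 0/1),
#'   NA for missing.
#' @param item_id a single item id, or a vector parallel to `response`.
#' @param items item-definition table from [ecdi_items()].
#' @return integer scores in \{0, 1\}, NA where the response is missing.
#' @export
#' @examples
#' apply_reverse_coding("yes", "gets_along")        # 1
#' apply_reverse_coding("yes", "kicks_bites_hits")  # 0 (reverse coded)
#' apply_reverse_coding("no", "easily_distracted")  # 1 (reverse coded)
apply_reverse_coding <- function(response, item_id, items = ecdi_items()) {
  unknown <- setdiff(unique(item_id), items$item_id)
  if (length(unknown))
    stop("unknown item_id: ", paste(unknown, collapse = ", "))
  yes <- parse_binary(response, "ECDI response")
  reversed <- items$reverse_coded[match(item_id, items$item_id)]
  if (length(reversed) == 1L) reversed <- rep(reversed, length(yes))
  as.integer(ifelse(reversed, !yes, yes))
}

#' Classify a domain score vector as low development
#'
#' A child is classified as "low development" in a domain when they score
#' zero on more than one of the domain's items, i.e. at least two failures.
#' The learning/cognition domain has two scored items (so low requires
#' failing both); the socioemotional domain has three.
#'
#' @param scores complete vector of 0/1 scores for the domain's in-scope
#'   items (length 2 for learning/cognition, 3 for socioemotional).
#' @param domain `"learning_cognition"` or `"socioemotional"`.
#' @return logical: TRUE if the child is low in the domain.
#' @export
#' @examples
#' score_domain(c(0, 0), "learning_cognition")     # TRUE
#' score_domain(c(0, 1), "learning_cognition")     # FALSE
#' score_domain(c(0, 0, 1), "socioemotional")      # TRUE
score_domain <- function(scores, domain = c("learning_cognition", "socioemotional")) {
  domain <- match.arg(domain)
  n_expected <- nrow(domain_items(domain))
  if (length(scores) != n_expected)
    stop(sprintf("domain %s expects %d scores, got %d",
                 domain, n_expected, length(scores)))
  if (anyNA(scores)) stop("scores must be complete for domain classification")
  if (!all(scores %in% c(0, 1))) stop("scores must be 0/1")
  sum(scores == 0) >= 2L
}

#' Classify one child's ECDI record
#'
#' Applies reverse coding to the five in-scope items and the
#' more-than-one-failure rule per domain. A child with any missing in-scope
#' item is excluded (missingness in literacy-numeracy or physical items does
#' not exclude, since those domains are never scored here).
#'
#' @param record a one-row data.frame (or named list) with `ecdi_<item_id>`
#'   entries for all ten items.
#' @param items item-definition table.
#' @return a list with `low_cognitive`, `low_socioemotional`, `low_either`
#'   (logical, NA when excluded) and `excluded`.
#' @seealso [classify_microdata()] for the vectorized version.
#' @export
classify_child <- function(record, items = ecdi_items()) {
  df <- as.data.frame(as.list(record), check.names = FALSE,
                      stringsAsFactors = FALSE)
  out <- classify_microdata(df, items)
  list(low_cognitive = out$low_cognitive, low_socioemotional = out$low_socioemotional,
       low_either = out$low_either, excluded = out$excluded)
}

#' Classify all children in a microdata table
#'
#' Vectorized scoring and classification. Appends four columns:
#' `low_cognitive`, `low_socioemotional`, `low_either` (0/1 coded as logical,
#' NA for excluded children) and `excluded`.
#'
#' @param microdata data.frame with one `ecdi_<item_id>` column per item,
#'   responses coded yes/no (or 0/1), empty/NA for missing.
#' @param items item-definition table.
#' @return the input data.frame with classification columns appended.
#' @export
classify_microdata <- function(microdata, items = ecdi_items()) {
  scope <- items[items$in_scope, , drop = FALSE]
  cols <- paste0("ecdi_", scope$item_id)
  missing_cols <- setdiff(cols, names(microdata))
  if (length(missing_cols))
    stop("microdata lacks ECDI columns: ", paste(missing_cols, collapse = ", "))
  n <- nrow(microdata)
  score_mat <- matrix(NA_integer_, n, nrow(scope),
                      dimnames = list(NULL, scope$item_id))
  for (j in seq_len(nrow(scope))) {
    score_mat[, j] <- apply_reverse_coding(microdata[[cols[j]]],
                                           scope$item_id[j], items)
  }
  excluded <- rowSums(is.na(score_mat)) > 0L
  cog_ids <- scope$item_id[scope$domain == "learning_cognition"]
  soc_ids <- scope$item_id[scope$domain == "socioemotional"]
  low_cog <- rowSums(score_mat[, cog_ids, drop = FALSE] == 0L) >= 2L
  low_soc <- rowSums(score_mat[, soc_ids, drop = FALSE] == 0L) >= 2L
  low_cog[excluded] <- NA
  low_soc[excluded] <- NA
  microdata$low_cognitive <- low_cog
  microdata$low_socioemotional <- low_soc
  microdata$low_either <- low_cog | low_soc
  microdata$excluded <- excluded
  microdata
}
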