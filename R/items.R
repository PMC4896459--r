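.items_cache <- new.env(parent = emptyenv())

#' ECDI item definitions
#'
#' The ten caregiver-reported yes/no items of the Early Childhood Development
#' Index (ECDI), with their developmental domain, reverse-coding flag, and
#' whether the item enters the low-development classification. Only the two
#' learning/cognition items and the three socioemotional items are in scope
#' for classification; the literacy-numeracy and physical items are carried
#' for completeness but never gate a child's inclusion.
#'
#' Reverse-coded items are those where a "yes" response indicates a problem
#' ("too sick to play", "kicks, bites, or hits", "easily distracted"), so
#' that after coding a score of 1 always means favorable.
#'
#' @param path optional path to an alternative item-definition JSON resource.
#' @return a data.frame with columns `item_id`, `label`, `domain`
#'   (`literacy_numeracy`, `learning_cognition`, `physical`,
#'   `socioemotional`), `reverse_coded`, `in_scope`.
#' @export
#' @examples
#' items <- ecdi_items()
#' items[items$in_scope, c("item_id", "domain", "reverse_coded")]
ecdi_items <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.items_cache$items)) return(.items_cache$items)
    path <- system.file("extdata", "ecdi_items.json", package = "ecdiglobal",
                        mustWork = TRUE)
    cache <- TRUE
  } else cache <- FALSE
  raw <- jsonlite::fromJSON(path)
  items <- raw$items
  validate_items(items)
  if (cache) .items_cache$items <- items
  items
}

validate_items <- function(items) {
  needed <- c("item_id", "domain", "reverse_coded", "in_scope")
  missing <- setdiff(needed, names(items))
  if (length(missing))
    stop("item definitions lack columns: ", paste(missing, collapse = ", "))
  if (nrow(items) != 10L) stop("expected exactly 10 ECDI items, got ", nrow(items))
  if (anyDuplicated(items$item_id)) stop("duplicated item_id in item definitions")
  if (sum(items$in_scope & items$domain == "learning_cognition") != 2L)
    stop("learning_cognition must have 2 in-scope items")
  if (sum(items$in_scope & items$domain == "socioemotional") != 3L)
    stop("socioemotional must have 3 in-scope items")
  if (any(items$in_scope & items$domain %in% c("literacy_numeracy", "physical")))
    stop("literacy_numeracy and physical items must be out of scope")
  invisible(items)
}

#' @rdname ecdi_items
#' @param domain a scored domain, `"learning_cognition"` or `"socioemotional"`.
#' @export
domain_items <- function(domain = c("learning_cognition", "socioemotional")) {
  domain <- match.arg(domain)
  items <- ecdi_items()
  items[items$in_scope & items$domain == domain, , drop = FALSE]
}
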