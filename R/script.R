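#' Default communicative style definitions
#'
#' Two styles are operationalized by default: a *neutral* style
#' ("concise, factual, and emotionally neutral") and an *enthusiastic*
#' style ("supportive, motivational, and positively expressive"). The
#' definition strings are inserted verbatim into the rephrasing prompt
#' built by [build_style_prompt()].
#'
#' @return named character vector mapping style name to definition.
#' @export
style_definitions <- function() {
  c(neutral      = "concise, factual, and emotionally neutral",
    enthusiastic = "supportive, motivational, and positively expressive")
}

#' Build the style-conditioned rephrasing prompt
#'
#' Composes the instruction string handed to a language model to
#' rephrase one script item in the selected communicative style. The
#' template is fixed:
#'
#' ```
#' Rephrase the following user-facing question in a [STYLE] manner,
#' as defined below. Do not alter the meaning or structure of the item.
#' Style definition: [STYLE DEFINITION]
#' Question: '[ORIGINAL ITEM]'
#' ```
#'
#' (three lines; the first two sentences share the first line). Only
#' the three placeholders are substituted. No model is called: the
#' function returns the string, and rendering is left to a pluggable
#' renderer (the default renderer is the identity on the item text).
#'
#' @param style style name (must be a name of `styles`).
#' @param item one script item: a list or one-row data.frame with
#'   `text`, or a bare string.
#' @param styles named character vector of style definitions, default
#'   [style_definitions()].
#' @return the prompt string.
#' @examples
#' cat(build_style_prompt("neutral", "I have a problem and I think
#' I should work on it."))
#' @export
build_style_prompt <- function(style, item, styles = style_definitions()) {
  if (!style %in% names(styles))
    stop("unknown style: ", style, " (known: ",
         paste(names(styles), collapse = ", "), ")", call. = FALSE)
  text <- if (is.character(item)) item
          else if (!is.null(item$text)) item$text
          else stop("item must be a string or have a $text field",
                    call. = FALSE)
  if (!nzchar(text)) stop("item text must be non-empty", call. = FALSE)
  paste0(
    "Rephrase the following user-facing question in a ", style,
    " manner, as defined below. Do not alter the meaning or structure of the item.\n",
    "Style definition: ", styles[[style]], "\n",
    "Question: '", text, "'"
  )
}

#' Placeholder interaction script
#'
#' Generates an ordered script of placeholder items standing in for a
#' real instrument (the intended use case is a 32-item
#' readiness-to-change questionnaire; its copyrighted item texts are
#' supplied by the user via [read_script()]). Placeholder texts are
#' neutral interrogative statements; items are answered on an integer
#' Likert scale.
#'
#' @param n_items number of items, default 32.
#' @param seed unused for the fixed placeholder texts but kept so that
#'   scripted pipelines can thread one seed everywhere.
#' @return data.frame with columns `id` (1..n) and `text`.
#' @export
make_default_script <- function(n_items = 32L, seed = NULL) {
  n_items <- as.integer(n_items)
  if (is.na(n_items) || n_items < 1L)
    stop("n_items must be a positive integer", call. = FALSE)
  data.frame(
    id = seq_len(n_items),
    text = sprintf(
      "Placeholder item %d: please rate how much you agree with statement %d on the scale provided.",
      seq_len(n_items), seq_len(n_items)),
    stringsAsFactors = FALSE
  )
}

validate_script <- function(script) {
  if (!is.data.frame(script) || !all(c("id", "text") %in% names(script)))
    stop("a script is a data.frame with columns id and text", call. = FALSE)
  if (nrow(script) == 0L) stop("script has no items", call. = FALSE)
  if (anyDuplicated(script$id))
    stop("duplicate item id(s): ",
         paste(unique(script$id[duplicated(script$id)]), collapse = ", "),
         call. = FALSE)
  if (any(!nzchar(script$text))) stop("empty item text", call. = FALSE)
  script$id <- as.integer(script$id)
  script
}

#' Read / write an interaction script
#'
#' Scripts are stored as a JSON array of `{"id": int, "text": str}`
#' objects; order, ids and text survive a round-trip exactly.
#'
#' @param path file path.
#' @return `read_script()` returns the script data.frame.
#' @export
read_script <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  if (is.null(dim(obj)))
    stop("script file must be a JSON array of {id, text} objects",
         call. = FALSE)
  validate_script(as.data.frame(obj, stringsAsFactors = FALSE))
}

#' @rdname read_script
#' @param script script data.frame with columns `id`, `text`.
#' @export
write_script <- function(script, path) {
  script <- validate_script(script)
  jsonlite::write_json(script[c("id", "text")], path, auto_unbox = FALSE,
                       digits = NA)
  invisible(path)
}
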