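# Prefix-prompt construction for a generative zero/few-shot baseline: the
# input sentence is followed by the list of admissible label phrases and a
# cloze-style lead-in, and generation begins where the prompt ends. If the
# tokenized prompt exceeds the model's context window the *sentence* is
# trimmed from its end; the scaffold (options + lead-in) is never touched.

#' Split a string into whitespace tokens
#'
#' The default token counter for [buildPrompt()]; a subword tokenizer for a
#' specific language model can be plugged in instead.
#'
#' @param x A single string.
#' @return Character vector of tokens (empty for a blank string).
#' @export
whitespaceTokenizer <- function(x) {
  x <- trimws(x)
  if (!nzchar(x)) return(character())
  strsplit(x, "\\s+")[[1L]]
}

#' Default clinical label phrases for the prompt options list
#'
#' The four advance-care-planning disease categories, in the printed
#' lowercase form used inside the prompt.
#'
#' @return Character vector of 4 label phrases.
#' @export
defaultLabelOptions <- function() {
  c("advanced cancer", "advanced heart disease",
    "advanced lung disease", "chronic pain fibromyalgia")
}

#' Build a prompt template
#'
#' @param labelOptions Ordered, non-empty character vector of label phrases
#'   shown as the options list (default [defaultLabelOptions()]).
#' @param maxContext Maximum prompt size in tokens (default 1024, the GPT-2
#'   context window).
#' @param tokenizer Function mapping a string to its token vector; only the
#'   token count is used (default [whitespaceTokenizer()]).
#' @return An object of class `"PromptTemplate"`.
#' @export
promptTemplate <- function(labelOptions = defaultLabelOptions(),
                           maxContext = 1024L,
                           tokenizer = whitespaceTokenizer) {
  labelOptions <- as.character(labelOptions)
  maxContext <- as.integer(maxContext)
  stopifnot(length(labelOptions) >= 1L, all(nzchar(labelOptions)),
            maxContext >= 1L, is.function(tokenizer))
  structure(list(labelOptions = labelOptions, maxContext = maxContext,
                 tokenizer = tokenizer),
            class = "PromptTemplate")
}

#' @export
print.PromptTemplate <- function(x, ...) {
  cat("PromptTemplate: ", length(x$labelOptions), " options, max ",
      x$maxContext, " tokens\n", sep = "")
  invisible(x)
}

promptScaffold <- function(template) {
  paste0(". options are ", paste(template$labelOptions, collapse = ", "),
         ". type of disease")
}

#' Build a prefix prompt for one input text
#'
#' Returns `"{text}. options are <label phrases>. type of disease"`; the
#' completion slot is implicit at the end of the string. If the tokenized
#' prompt exceeds `maxContext`, tokens are dropped from the end of the input
#' text (never from the scaffold) until it fits.
#'
#' @param text Non-empty input sentence.
#' @param template A `"PromptTemplate"` from [promptTemplate()].
#' @return The prompt string.
#' @examples
#' buildPrompt("needs palliative consult", promptTemplate())
#' @export
buildPrompt <- function(text, template = promptTemplate()) {
  stopifnot(inherits(template, "PromptTemplate"))
  if (!is.character(text) || length(text) != 1L || !nzchar(trimws(text)))
    stop("text must be a single non-empty string")
  scaffold <- promptScaffold(template)
  nScaffold <- length(template$tokenizer(scaffold))
  if (nScaffold > template$maxContext)
    stop("the prompt scaffold alone (", nScaffold,
         " tokens) exceeds maxContext (", template$maxContext, ")")
  prompt <- paste0(text, scaffold)
  if (length(template$tokenizer(prompt)) <= template$maxContext)
    return(prompt)
  # trim the sentence from its end, whole whitespace tokens at a time
  words <- whitespaceTokenizer(text)
  hi <- length(words)
  while (hi > 0L) {
    candidate <- paste0(paste(words[seq_len(hi)], collapse = " "), scaffold)
    if (length(template$tokenizer(candidate)) <= template$maxContext)
      return(candidate)
    hi <- hi - 1L
  }
  scaffoldOnly <- sub("^\\. ", "", scaffold)
  if (length(template$tokenizer(scaffoldOnly)) <= template$maxContext)
    return(scaffoldOnly)
  stop("input text cannot be trimmed to fit maxContext")
}

#' Build prompts for a whole corpus
#'
#' @param corpus A `data.frame` with a `text` column (see [readCorpus()]).
#' @param template A `"PromptTemplate"`.
#' @return Character vector of prompts, one per corpus row.
#' @export
buildPrompts <- function(corpus, template = promptTemplate()) {
  vapply(as.character(corpus$text), buildPrompt, character(1L),
         template = template, USE.NAMES = FALSE)
}
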