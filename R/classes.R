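# Diagnostic classes and the highest-risk labelling rule.

#' Risk-ordered diagnostic classes
#'
#' The four histological classes of the esophageal classification task, in
#' increasing clinical risk: normal squamous/columnar tissue, Barrett
#' esophagus without dysplasia, Barrett esophagus with dysplasia, and
#' esophageal adenocarcinoma.  The order defines both the highest-risk
#' labelling rule and the tie-break used when predicted probabilities are
#' exactly equal (the lower-risk class wins a tie, a deliberately
#' conservative and deterministic rule).
#'
#' @return character vector of length 4, lowest risk first
#' @export
#' @examples
#' class_order()
class_order <- function() {
  c("normal", "BE-no-dysplasia", "BE-with-dysplasia", "adenocarcinoma")
}

validate_classes <- function(x) {
  bad <- setdiff(unique(as.character(x)), class_order())
  if (length(bad) > 0) {
    stop("unknown class name(s): ", paste(bad, collapse = ", "),
         "; expected one of: ", paste(class_order(), collapse = ", "))
  }
  invisible(TRUE)
}

#' Assign a tissue-level label from its lesion classes
#'
#' A tissue containing several lesions of different classes receives the
#' class with the highest clinical risk; a tissue with no lesions is normal.
#'
#' @param lesion_classes character vector of lesion classes (possibly empty);
#'   a data frame with a `class` column is also accepted
#' @param order risk-ordered class vector; defaults to [class_order()]
#' @return single class label (character)
#' @export
#' @examples
#' assign_label(character(0))                      # "normal"
#' assign_label(c("BE-no-dysplasia", "adenocarcinoma"))
assign_label <- function(lesion_classes, order = class_order()) {
  if (is.data.frame(lesion_classes)) lesion_classes <- lesion_classes$class
  lesion_classes <- as.character(lesion_classes)
  if (length(lesion_classes) == 0) return(order[1])
  bad <- setdiff(unique(lesion_classes), order)
  if (length(bad) > 0) {
    stop("unknown class name(s): ", paste(bad, collapse = ", "))
  }
  order[max(match(lesion_classes, order))]
}

# Risk rank of a class (1 = lowest risk).
class_rank <- function(x, order = class_order()) match(as.character(x), order)
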