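#' @import methods
#' @importFrom stats sd var cor cor.test t.test var.test anova lm rnorm runif
#'   quantile complete.cases setNames
#' @importFrom utils read.csv write.csv head
NULL

# canonical vocabularies for the plate data model
.WELL_ROLES <- c("test", "positive_control", "negative_control",
                 "endothelial_only_blank", "standard_curve")
.READ_STAGES <- c("pre_wash", "wash1", "wash2", "wash3")
.WELL_REGEX <- "^[A-H](1[0-2]|[1-9])$"

.isValidWell <- function(well) grepl(.WELL_REGEX, well)

# all 96 well labels in row-major (A1..A12, B1..) order
.wellGrid <- function() {
  paste0(rep(LETTERS[1:8], each = 12L), rep(1:12, times = 8L))
}

.stopf <- function(fmt, ..., class) {
  msg <- sprintf(fmt, ...)
  cnd <- structure(
    class = c(class, "twinLEA_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  )
  stop(cnd)
}

.schemaError     <- function(fmt, ...) .stopf(fmt, ..., class = "twinLEA_schema_error")
.validationError <- function(fmt, ...) .stopf(fmt, ..., class = "twinLEA_validation_error")
.domainError     <- function(fmt, ...) .stopf(fmt, ..., class = "twinLEA_domain_error")

.assertScalarNumber <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    .domainError("'%s' must be a single finite number", name)
  invisible(x)
}

.requireColumns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    .schemaError("%s is missing required column(s): %s",
                 what, paste(missing, collapse = ", "))
  invisible(df)
}

# collapse a character vector for error messages, capped
.fmtSome <- function(x, n = 5L) {
  x <- unique(x)
  if (length(x) > n) paste0(paste(head(x, n), collapse = ", "), ", ...")
  else paste(x, collapse = ", ")
}
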