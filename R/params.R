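#' EEM parameter sets
#'
#' An EEM parameter set couples an atom-typing scheme, the dimensionless
#' electrostatic adjusting factor k (Yang--Wang modification), and one
#' (A, B) pair per atom type. A is the effective electronegativity of the
#' neutral typed atom corrected for the molecular environment; B is twice
#' its effective hardness, i.e. the response of electronegativity to
#' charge. Both are on the (arbitrary) electronegativity scale of the
#' calibration targets.
#'
#' @param scheme Atom typing scheme, `"E"` or `"EX"`.
#' @param k Positive adjusting factor for the interatomic electrostatic
#'   term.
#' @param table A data.frame with columns `type`, `A`, `B` (one row per
#'   atom type), or a named list of `c(A, B)` pairs.
#'
#' @return An object of class `eem_params`.
#' @export
eem_params <- function(scheme = c("E", "EX"), k, table) {
  scheme <- match.arg(scheme)
  if (!is.numeric(k) || length(k) != 1L || !is.finite(k) || k <= 0) {
    stop("k must be a single positive finite number")
  }
  if (is.list(table) && !is.data.frame(table)) {
    table <- data.frame(type = names(table),
                        A = vapply(table, `[`, numeric(1), 1L),
                        B = vapply(table, `[`, numeric(1), 2L),
                        stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(table),
            all(c("type", "A", "B") %in% names(table)))
  table <- data.frame(type = as.character(table$type),
                      A = as.numeric(table$A), B = as.numeric(table$B),
                      stringsAsFactors = FALSE)
  rownames(table) <- NULL
  if (anyDuplicated(table$type)) stop("duplicate atom type in parameter table")
  if (!all(is.finite(table$A)) || !all(is.finite(table$B))) {
    stop("non-finite A or B parameter")
  }
  if (any(table$B <= 0)) {
    stop("B must be positive (effective hardness) for type(s): ",
         paste(table$type[table$B <= 0], collapse = ", "))
  }
  structure(list(scheme = scheme, k = k, table = table),
            class = "eem_params")
}

#' @export
print.eem_params <- function(x, ...) {
  cat("EEM parameters: scheme '", x$scheme, "', k = ",
      format(x$k), ", ", nrow(x$table), " atom types\n", sep = "")
  print(x$table, row.names = FALSE)
  invisible(x)
}

# (A, B) lookup for a vector of type keys; errors name the missing type.
params_for_types <- function(params, types) {
  idx <- match(types, params$table$type)
  if (anyNA(idx)) {
    missing <- unique(types[is.na(idx)])
    stop("no EEM parameters for atom type(s): ",
         paste(missing, collapse = ", "))
  }
  list(A = params$table$A[idx], B = params$table$B[idx])
}

#' Read / write EEM parameter files
#'
#' Plain-text key-value format: header lines `scheme: E|EX` and
#' `k: <float>`, then one line per atom type,
#' `TYPE <key> A=<float> B=<float>`. Values are written with nine decimals
#' so that write/read round-trips are exact at that precision.
#'
#' @param path Path to a parameter file.
#' @return For `read_eem_params`, an [eem_params()] object.
#' @export
read_eem_params <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  get_header <- function(key) {
    m <- grep(paste0("^", key, ":"), lines, value = TRUE)
    if (length(m) != 1L) stop("parameter file must have exactly one '",
                              key, ":' line: ", path)
    trimws(sub(paste0("^", key, ":"), "", m))
  }
  scheme <- get_header("scheme")
  k <- as.numeric(get_header("k"))
  tl <- grep("^TYPE ", lines, value = TRUE)
  if (length(tl) == 0L) stop("parameter file has no TYPE lines: ", path)
  parts <- strsplit(tl, "[ \t]+")
  table <- data.frame(
    type = vapply(parts, `[`, character(1), 2L),
    A = as.numeric(sub("^A=", "", vapply(parts, `[`, character(1), 3L))),
    B = as.numeric(sub("^B=", "", vapply(parts, `[`, character(1), 4L))),
    stringsAsFactors = FALSE
  )
  eem_params(scheme = scheme, k = k, table = table)
}

#' @rdname read_eem_params
#' @param params An [eem_params()] object.
#' @export
write_eem_params <- function(params, path) {
  lines <- c(
    paste0("scheme: ", params$scheme),
    paste0("k: ", sprintf("%.9f", params$k)),
    sprintf("TYPE %s A=%.9f B=%.9f",
            params$table$type, params$table$A, params$table$B)
  )
  writeLines(lines, path)
  invisible(path)
}
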