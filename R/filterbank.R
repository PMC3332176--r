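#' Wavelet filter banks
#'
#' A filter bank carries the four finite impulse responses of a two-channel
#' perfect-reconstruction filter pair: decomposition low/high pass and
#' reconstruction low/high pass. Built-in banks are the orthonormal Haar,
#' Daubechies 4 and Coiflets 3 families and the biorthogonal 6.8 pair,
#' with the canonical published coefficients. Further families (for example
#' atomic-function wavelets, whose coefficients are not published) can be
#' supplied as plain-text coefficient files via [read_filter_bank()].
#'
#' @param name One of `"haar"`, `"db4"`, `"coif3"`, `"bior6.8"`.
#' @return An object of class `filter_bank`: a list with elements `name`,
#'   `dec_lo`, `dec_hi`, `rec_lo`, `rec_hi` and logical `orthogonal`.
#' @examples
#' fb <- wavelet_filter("haar")
#' fb$dec_lo
#' @export
wavelet_filter <- function(name) {
  if (inherits(name, "filter_bank")) return(name)
  stopifnot(is.character(name), length(name) == 1L)
  fb <- .filter_registry[[name]]
  if (is.null(fb)) {
    stop("unknown wavelet family '", name, "'; built-ins are: ",
         paste(names(.filter_registry), collapse = ", "),
         ". Use read_filter_bank() for user-supplied coefficients.",
         call. = FALSE)
  }
  fb
}

#' @rdname wavelet_filter
#' @export
list_wavelet_filters <- function() names(.filter_registry)

new_filter_bank <- function(name, dec_lo, dec_hi, rec_lo, rec_hi,
                            orthogonal = NA) {
  for (f in list(dec_lo, dec_hi, rec_lo, rec_hi)) {
    if (length(f) == 0L || !all(is.finite(f)))
      stop("filter coefficient sequences must be non-empty and finite",
           call. = FALSE)
  }
  if (is.na(orthogonal)) {
    # orthonormal iff analysis and synthesis low-pass agree up to reversal
    orthogonal <- length(dec_lo) == length(rec_lo) &&
      max(abs(rev(dec_lo) - rec_lo)) < 1e-12 &&
      abs(sum(dec_lo^2) - 1) < 1e-10
  }
  structure(list(name = name,
                 dec_lo = as.numeric(dec_lo), dec_hi = as.numeric(dec_hi),
                 rec_lo = as.numeric(rec_lo), rec_hi = as.numeric(rec_hi),
                 orthogonal = orthogonal),
            class = "filter_bank")
}

#' Read a filter bank from a plain-text coefficient file
#'
#' The file holds four named sections, one coefficient per line:
#' a section starts with the bare word `dec_lo`, `dec_hi`, `rec_lo`
#' or `rec_hi`; the lines after it (until the next section) are numbers.
#' Blank lines and `#` comments are ignored. This is the route for
#' wavelet families whose coefficients the user supplies, e.g. atomic
#' function wavelets.
#'
#' @param path Path to the coefficient file.
#' @param name Identifier stored in the bank; default the file name.
#' @return A `filter_bank`.
#' @export
read_filter_bank <- function(path, name = basename(path)) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  sections <- c("dec_lo", "dec_hi", "rec_lo", "rec_hi")
  out <- stats::setNames(vector("list", 4L), sections)
  current <- NULL
  for (ln in lines) {
    if (ln %in% sections) {
      current <- ln
    } else {
      if (is.null(current))
        stop("coefficient before any section header in ", path, call. = FALSE)
      val <- suppressWarnings(as.numeric(ln))
      if (is.na(val))
        stop("cannot parse coefficient line '", ln, "' in ", path,
             call. = FALSE)
      out[[current]] <- c(out[[current]], val)
    }
  }
  missing <- sections[vapply(out, is.null, logical(1L))]
  if (length(missing))
    stop("filter file ", path, " lacks section(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  new_filter_bank(name, out$dec_lo, out$dec_hi, out$rec_lo, out$rec_hi)
}

#' @export
print.filter_bank <- function(x, ...) {
  cat("<filter_bank> ", x$name, ": ", length(x$dec_lo), " taps, ",
      if (isTRUE(x$orthogonal)) "orthogonal" else "biorthogonal", "\n",
      sep = "")
  invisible(x)
}

# Canonical two-channel filter coefficients (analysis/synthesis), in the
# convention where the analysis step is convolution + dyadic decimation.
.filter_registry <- local({
  sq2 <- sqrt(2) / 2
  db4_lo <- c(-0.010597401785069032, 0.0328830116668852,
              0.030841381835560764, -0.18703481171909309,
              -0.027983769416859854, 0.6308807679298589,
              0.7148465705529157, 0.2303778133088965)
  coif3_lo <- c(-3.459977319727278e-05, -7.0983302506379e-05,
                0.0004662169598204029, 0.0011175187708306303,
                -0.0025745176881367972, -0.009007976136730624,
                0.015880544863669452, 0.03455502757329774,
                -0.08230192710629983, -0.07179982161915484,
                0.42848347637737, 0.7937772226260872,
                0.40517690240911824, -0.06112339000297255,
                -0.06577191128146936, 0.023452696142077168,
                0.007782596425672746, -0.003793512864380802)
  # quadrature-mirror construction: high-pass filters are the alternating-sign
  # modulation of the opposite branch's low-pass
  qmf_highpass <- function(rec_lo, dec_lo) {
    L <- length(rec_lo)
    list(dec_hi = rec_lo * rep_len(c(-1, 1), L),
         rec_hi = dec_lo * rep_len(c(1, -1), L))
  }
  qmf_bank <- function(name, dec_lo) {
    rec_lo <- rev(dec_lo)
    hi <- qmf_highpass(rec_lo, dec_lo)
    new_filter_bank(name, dec_lo, hi$dec_hi, rec_lo, hi$rec_hi,
                    orthogonal = TRUE)
  }
  bior68_dec_lo <- c(0, 0.0019088317364812906, -0.0019142861290887667,
                     -0.016990639867602342, 0.01193456527972926,
                     0.04973290349094079, -0.07726317316720414,
                     -0.09405920349573646, 0.4207962846098268,
                     0.8259229974584023, 0.4207962846098268,
                     -0.09405920349573646, -0.07726317316720414,
                     0.04973290349094079, 0.01193456527972926,
                     -0.016990639867602342, -0.0019142861290887667,
                     0.0019088317364812906)
  bior68_rec_lo <- c(0, 0, 0, 0.014426282505624435, 0.014467504896790148,
                     -0.07872200106262882, -0.04036797903033992,
                     0.41784910915027457, 0.7589077294536541,
                     0.41784910915027457, -0.04036797903033992,
                     -0.07872200106262882, 0.014467504896790148,
                     0.014426282505624435, 0, 0, 0, 0)
  bior68_hi <- qmf_highpass(bior68_rec_lo, bior68_dec_lo)
  bior68_dec_hi <- bior68_hi$dec_hi
  bior68_rec_hi <- bior68_hi$rec_hi
  list(
    haar = qmf_bank("haar", c(sq2, sq2)),
    db4 = qmf_bank("db4", db4_lo),
    coif3 = qmf_bank("coif3", coif3_lo),
    bior6.8 = new_filter_bank("bior6.8", bior68_dec_lo, bior68_dec_hi,
                              bior68_rec_lo, bior68_rec_hi,
                              orthogonal = FALSE)
  )
})
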