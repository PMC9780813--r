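# Record and label input/output. WFDB dialect implemented: format-16
# little-endian integer samples with gain/baseline taken from the header
# (the dialect used by 100 Hz PTB-XL records); any other sample format is
# rejected with an explicit message.

#' Read a WFDB record (.hea/.dat pair, format 16)
#'
#' @param path Path to the record, with or without the `.hea` extension.
#' @return An [EcgRecord-class]; samples are converted to mV using each
#'   signal's gain and baseline.
#' @export
readRecord <- function(path) {
  hea <- if (grepl("\\.hea$", path)) path else paste0(path, ".hea")
  if (!file.exists(hea)) stop("header file not found: ", hea)
  lines <- readLines(hea, warn = FALSE)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (!length(lines)) stop("corrupt header: no record line in ", hea)

  rec <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  if (length(rec) < 4L)
    stop("corrupt header: record line needs 'name nsig fs nsamples', got '",
         lines[1L], "'")
  id <- basename(rec[1L])
  nsig <- suppressWarnings(as.integer(rec[2L]))
  fs <- suppressWarnings(as.numeric(rec[3L]))
  nsamp <- suppressWarnings(as.integer(rec[4L]))
  if (is.na(nsig) || nsig < 1L) stop("corrupt header: bad signal count field")
  if (is.na(fs) || fs <= 0) stop("corrupt header: bad sampling-rate field")
  if (is.na(nsamp) || nsamp < 1L) stop("corrupt header: bad sample-count field")
  if (length(lines) < 1L + nsig)
    stop("corrupt header: ", nsig, " signal lines declared, ",
         length(lines) - 1L, " present")

  datFile <- character(nsig)
  fmt <- integer(nsig)
  gain <- numeric(nsig)
  baseline <- numeric(nsig)
  leadName <- character(nsig)
  for (k in seq_len(nsig)) {
    f <- strsplit(trimws(lines[1L + k]), "\\s+")[[1L]]
    if (length(f) < 3L)
      stop("corrupt header: signal line ", k, " too short")
    datFile[k] <- f[1L]
    fmt[k] <- suppressWarnings(as.integer(sub("[^0-9].*$", "", f[2L])))
    # gain spec: gain(baseline)/units, each part optional
    gspec <- f[3L]
    gain[k] <- suppressWarnings(as.numeric(sub("[(/].*$", "", gspec)))
    if (is.na(gain[k]) || gain[k] == 0) gain[k] <- 200  # WFDB default gain
    bl <- regmatches(gspec, regexpr("\\(-?[0-9]+\\)", gspec))
    baseline[k] <- if (length(bl)) as.numeric(gsub("[()]", "", bl)) else 0
    leadName[k] <- if (length(f) >= 9L) f[length(f)] else paste0("sig", k)
  }
  if (any(is.na(fmt)))
    stop("corrupt header: unreadable sample-format field")
  if (any(fmt != 16L))
    stop("unsupported WFDB sample format(s) ",
         paste(unique(fmt[fmt != 16L]), collapse = ", "),
         "; only format 16 is supported")
  if (length(unique(datFile)) != 1L)
    stop("multi-file records are not supported")

  dat <- file.path(dirname(hea), datFile[1L])
  if (!file.exists(dat)) stop("signal file not found: ", dat)
  raw <- readBin(dat, what = "integer", size = 2L, signed = TRUE,
                 endian = "little", n = file.size(dat) / 2L + 1L)
  if (length(raw) != nsig * nsamp)
    stop("length mismatch: header declares ", nsig, " x ", nsamp, " = ",
         nsig * nsamp, " samples but ", dat, " holds ", length(raw))
  m <- matrix(raw, nrow = nsig)  # samples interleaved across signals
  sig <- t((m - baseline) / gain)
  if (anyDuplicated(leadName))
    leadName <- make.unique(leadName)
  EcgRecord(id = id, signals = sig, fs = fs, leads = leadName)
}

#' Write a record as a WFDB format-16 .hea/.dat pair
#'
#' @param record An [EcgRecord-class].
#' @param dir Output directory (created if missing).
#' @param gain ADC gain: units per mV (default 1000, quantization 1 uV).
#' @return The header path, invisibly.
#' @export
writeRecord <- function(record, dir, gain = 1000) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  id <- record@id
  sig <- record@signals
  nsig <- ncol(sig)
  nsamp <- nrow(sig)
  q <- round(sig * gain)
  if (any(abs(q) > 32767))
    stop("signal exceeds the int16 range at gain ", gain)
  hea <- file.path(dir, paste0(id, ".hea"))
  dat <- paste0(id, ".dat")
  header <- c(
    paste(id, nsig, format(record@fs, scientific = FALSE), nsamp),
    sprintf("%s 16 %g(0)/mV 16 0 %d 0 0 %s", dat, gain,
            as.integer(q[1L, ]), record@leads))
  writeLines(header, hea)
  interleaved <- as.integer(t(q))
  writeBin(interleaved, file.path(dir, dat), size = 2L, endian = "little")
  invisible(hea)
}

#' Extract a single lead
#'
#' @param record An [EcgRecord-class].
#' @param lead Lead name (case-sensitive match against [leadNames()]).
#' @return List with `samples` (numeric vector, unchanged values) and
#'   `fs` (Hz).
#' @export
selectLead <- function(record, lead) {
  j <- match(lead, record@leads)
  if (is.na(j))
    stop("unknown lead '", lead, "'; available: ",
         paste(record@leads, collapse = ", "))
  list(samples = record@signals[, j], fs = record@fs)
}

#' Resample a signal (Fourier method, anti-aliased)
#'
#' Band-limited sampling-rate conversion in the frequency domain: the FFT
#' of the input is truncated or zero-padded to the output length, so content
#' below half the lower of the two rates is preserved and no aliasing is
#' introduced. Output length is `round(length(x) * fsOut / fsIn)`.
#'
#' @param x Numeric vector of samples.
#' @param fsIn,fsOut Input and output sampling rates in Hz.
#' @return Numeric vector of resampled values.
#' @export
resampleSignal <- function(x, fsIn, fsOut) {
  if (!length(x)) stop("cannot resample an empty signal")
  if (fsIn <= 0 || fsOut <= 0) stop("sampling rates must be > 0")
  n <- length(x)
  m <- as.integer(round(n * fsOut / fsIn))
  if (m < 1L) stop("output would be empty at rate ", fsOut)
  if (m == n) return(x)
  X <- fft(x)
  Y <- complex(length.out = m)
  if (m < n) {
    h <- m %/% 2L
    if (m %% 2L == 1L) {
      Y[1L:(h + 1L)] <- X[1L:(h + 1L)]
      if (h > 0L) Y[(m - h + 1L):m] <- X[(n - h + 1L):n]
    } else {
      Y[1L:h] <- X[1L:h]
      # the two source bins that fold onto the new Nyquist frequency are
      # conjugates, so their sum keeps the output real
      Y[h + 1L] <- X[h + 1L] + X[n - h + 1L]
      if (h > 1L) Y[(m - h + 2L):m] <- X[(n - h + 2L):n]
    }
  } else {
    h <- n %/% 2L
    if (n %% 2L == 1L) {
      Y[1L:(h + 1L)] <- X[1L:(h + 1L)]
      if (h > 0L) Y[(m - h + 1L):m] <- X[(n - h + 1L):n]
    } else {
      Y[1L:h] <- X[1L:h]
      Y[h + 1L] <- X[h + 1L] / 2  # split the old Nyquist bin symmetrically
      Y[m - h + 1L] <- X[h + 1L] / 2
      if (h > 1L) Y[(m - h + 2L):m] <- X[(n - h + 2L):n]
    }
  }
  Re(fft(Y, inverse = TRUE)) / n
}

#' Parse a metadata table into ASMI/NORM labels
#'
#' Applies the labelling rule: records whose diagnostic-code set contains
#' ASMI go to class ASMI and every other record goes to NORM. Set
#' `strictNorm = TRUE` to instead restrict NORM to records explicitly coded
#' NORM (dropping other pathologies).
#'
#' @param metadata Path to a CSV file, or a `data.frame`, with columns
#'   `record_id` and `scp_codes`; `scp_codes` is a textual code-to-weight
#'   map such as `"{'ASMI': 100.0, 'SR': 0.0}"`.
#' @param strictNorm Logical; see above. Default `FALSE` (verbatim rule).
#' @return `data.frame` with columns `record_id`, `class`.
#' @export
parseLabels <- function(metadata, strictNorm = FALSE) {
  df <- if (is.character(metadata)) read.csv(metadata,
                                             stringsAsFactors = FALSE)
        else as.data.frame(metadata)
  need <- c("record_id", "scp_codes")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("metadata lacks required column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$record_id)) stop("record ids must be unique")
  codesOf <- function(s) {
    m <- gregexpr("[A-Za-z0-9_]+(?=\\s*['\"]?\\s*:)", s, perl = TRUE)
    regmatches(s, m)[[1L]]
  }
  codeList <- lapply(as.character(df$scp_codes), codesOf)
  cls <- vapply(codeList, function(cd) {
    if ("ASMI" %in% cd) "ASMI" else "NORM"
  }, "")
  out <- data.frame(record_id = as.character(df$record_id), class = cls,
                    stringsAsFactors = FALSE)
  if (strictNorm) {
    isNorm <- vapply(codeList, function(cd) "NORM" %in% cd, NA)
    out <- out[out$class == "ASMI" | isNorm, , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}
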