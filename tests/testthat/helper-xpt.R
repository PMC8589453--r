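# Minimal SAS XPORT (version 5) writer, used only to build a small binary
# fixture at test time (the NHANES distribution format) for round-trip
# reading through foreign::read.xport. Numeric-only columns.

xpt_pad80 <- function(s) {
  raw <- charToRaw(s)
  stopifnot(length(raw) <= 80)
  c(raw, charToRaw(strrep(" ", 80 - length(raw))))
}

xpt_short <- function(x) {
  x <- as.integer(x)
  as.raw(c(x %/% 256L, x %% 256L))
}

xpt_long <- function(x) {
  x <- as.integer(x)
  as.raw(c(x %/% 16777216L %% 256L, x %/% 65536L %% 256L,
           x %/% 256L %% 256L, x %% 256L))
}

# Encode a double as an 8-byte IBM System/360 hexadecimal float.
xpt_ibm_double <- function(x) {
  if (is.na(x) || x == 0) {
    out <- as.raw(rep(0, 8))
    if (is.na(x)) out[1] <- as.raw(0x2e)  # SAS '.' missing value
    return(out)
  }
  sign <- if (x < 0) 1L else 0L
  ax <- abs(x)
  e <- floor(log(ax) / log(16)) + 1
  f <- ax / 16^e
  while (f >= 1) { e <- e + 1; f <- ax / 16^e }
  while (f < 1 / 16) { e <- e - 1; f <- ax / 16^e }
  digits <- integer(14)
  m <- f
  for (i in 1:14) {
    m <- m * 16
    digits[i] <- floor(m)
    m <- m - digits[i]
  }
  bytes <- integer(7)
  for (i in 1:7) bytes[i] <- digits[2 * i - 1] * 16L + digits[2 * i]
  as.raw(c(sign * 128L + (e + 64L), bytes))
}

xpt_namestr <- function(name, varnum, pos) {
  out <- raw(140)
  out[1:2] <- xpt_short(1)            # numeric
  out[3:4] <- xpt_short(0)
  out[5:6] <- xpt_short(8)            # 8-byte value
  out[7:8] <- xpt_short(varnum)
  nm <- toupper(substr(name, 1, 8))
  out[9:16] <- charToRaw(formatC(nm, width = 8, flag = "-"))
  out[17:56] <- charToRaw(strrep(" ", 40))
  out[57:64] <- charToRaw(strrep(" ", 8))
  out[65:70] <- as.raw(rep(0, 6))
  out[71:72] <- charToRaw("  ")
  out[73:80] <- charToRaw(strrep(" ", 8))
  out[81:84] <- as.raw(rep(0, 4))
  out[85:88] <- xpt_long(pos)
  out[89:140] <- charToRaw(strrep(" ", 52))
  out
}

write_xpt_fixture <- function(df, path) {
  stopifnot(all(vapply(df, is.numeric, TRUE)))
  date16 <- "16FEB11:10:20:06"
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- function(s) writeBin(xpt_pad80(s), con)
  hdr(paste0("HEADER RECORD*******LIBRARY HEADER RECORD!!!!!!!",
             "000000000000000000000000000000"))
  hdr(paste0("SAS     SAS     SASLIB  6.06    bsd4.2  ",
             strrep(" ", 24), date16))
  hdr(date16)
  hdr(paste0("HEADER RECORD*******MEMBER  HEADER RECORD!!!!!!!",
             "000000000000000001600000000140"))
  hdr(paste0("HEADER RECORD*******DSCRPTR HEADER RECORD!!!!!!!",
             "000000000000000000000000000000"))
  hdr(paste0("SAS     COHORT  SASDATA 6.06    bsd4.2  ",
             strrep(" ", 24), date16))
  hdr(paste0(date16, strrep(" ", 16), strrep(" ", 40), "        "))
  hdr(paste0("HEADER RECORD*******NAMESTR HEADER RECORD!!!!!!!",
             "000000", formatC(ncol(df), width = 4, flag = "0"),
             "00000000000000000000"))
  namestrs <- raw(0)
  for (j in seq_along(df)) {
    namestrs <- c(namestrs, xpt_namestr(names(df)[j], j, (j - 1) * 8))
  }
  pad <- (80 - length(namestrs) %% 80) %% 80
  namestrs <- c(namestrs, charToRaw(strrep(" ", pad)))
  writeBin(namestrs, con)
  hdr(paste0("HEADER RECORD*******OBS     HEADER RECORD!!!!!!!",
             "000000000000000000000000000000"))
  obs <- raw(0)
  for (i in seq_len(nrow(df))) {
    for (j in seq_along(df)) {
      obs <- c(obs, xpt_ibm_double(df[[j]][i]))
    }
  }
  pad <- (80 - length(obs) %% 80) %% 80
  obs <- c(obs, charToRaw(strrep(" ", pad)))
  writeBin(obs, con)
  invisible(path)
}
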