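# Build a small XLSX fixture workbook at test time (the system python
# carries openpyxl).  Each sheet is passed through a CSV intermediate.
make_xlsx_fixture <- function(path, sheets) {
  tmp <- tempfile()
  dir.create(tmp)
  csvs <- character(length(sheets))
  for (i in seq_along(sheets)) {
    csvs[i] <- file.path(tmp, paste0(i, ".csv"))
    utils::write.csv(sheets[[i]], csvs[i], row.names = FALSE)
  }
  script <- file.path(tmp, "mk.py")
  writeLines(c(
    "import csv, sys",
    "from openpyxl import Workbook",
    "wb = Workbook(); wb.remove(wb.active)",
    "names = sys.argv[1].split('|')",
    "for name, path in zip(names, sys.argv[2:]):",
    "    ws = wb.create_sheet(title=name)",
    "    with open(path) as fh:",
    "        for row in csv.reader(fh):",
    "            out = []",
    "            for v in row:",
    "                try:",
    "                    out.append(int(v))",
    "                except ValueError:",
    "                    try:",
    "                        out.append(float(v))",
    "                    except ValueError:",
    "                        out.append(v)",
    "            ws.append(out)",
    paste0("wb.save('", path, "')")), script)
  status <- system2("python", c(script,
                                shQuote(paste(names(sheets), collapse = "|")),
                                csvs),
                    stdout = TRUE, stderr = TRUE)
  if (!file.exists(path))
    stop("fixture workbook not created: ", paste(status, collapse = "\n"))
  path
}

# workbook representation of an interval_collection, 1-based inclusive
peaks_to_sheet <- function(x) {
  df <- as.data.frame(x)
  df$start <- df$start + 1L
  if (!is.null(df$summit)) df$summit <- df$summit + 1L
  df
}
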