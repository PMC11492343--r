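# psichart

Automated chart checks for low-dose-rate (LDR) prostate brachytherapy
documentation.

## The problem

A prostate seed implant (PSI) produces a stack of chart documents in the
radiation oncology information system — the prescription, the CT volume
study report, the intra-procedure quality checklist, the post-implant
radiation survey report and the end-of-treatment note, 133 data points in
all. Physicists verify these by hand at two moments: when seeds are
ordered, and during the monthly audit of completed implants. The checks
are mechanical (is every mandatory field filled in? do the documents agree
with each other? is every value inside its institutional limit?) and
therefore automatable wherever the documentation is digital.

`psichart` is a schema-driven engine for exactly those checks. It parses
Word (DOCX) and text-layer PDF chart documents into typed fields and runs
three layers of rules:

1. **Data completeness** — every required field is present, parses under
   its declared type, and equals its expected constant where one exists
   (e.g. source activity must read 0.36 mCi).
2. **Cross-document consistency** — data points recorded in several
   documents must agree (prostate volume in prescription vs. volume study;
   implanted seed counts in quality checklist vs. survey report vs.
   end-of-treatment note). A discrepancy additionally *triggers* a full
   completeness pass over every involved document, so the report explains
   it.
3. **Allowable value range** — numeric values must lie inside inclusive
   institutional limits, and the physician's manually entered seed order
   is verified against the institutional nomogram.

### The seed nomogram

The bundled nomogram maps prostate volume (10–80 cm³ in 5 cm³ steps) and
prescription dose (145 Gy definitive, or 110 Gy boost after 45 Gy EBRT) to
the average number of I-125 seeds required at 0.36 mCi per seed; values
between rows are interpolated linearly. With `m` the manual order, `s(V, D)`
the nomogram value and tolerance `t = 5` seeds:

```
d = m − s(V, D)
d >  t  → WARNING  (physicist verification)
d < −t  → ERROR    (immediate attention and investigation)
|d| ≤ t → PASS
```

Orders are placed in increments of 5, so the generator's seed-order field
is `s(V, D)` rounded **up** to the next multiple of 5 (never under-order).

Content the engine cannot read — reports pasted into the EMR as PNG
images, scanned PDFs — is never guessed at: the affected fields are
flagged for manual inspection, mirroring the non-OCR scope of the tool.

## A worked example

```r
library(psichart)

params <- chart_params("P001", prostate_volume = 30, dose = 145)
generate_chart(params, "demo_chart", formats = c("docx", "pdf"))

chart   <- load_chart("demo_chart")
results <- run_process(chart, "seed_ordering")
report  <- summary_report(results, "seed_ordering", chart$patient_id)
cat(render_report(report, "text"))
```

```
=== PSI chart check report ===
Patient: P001    Process: seed_ordering    Time: 2026-01-02T03:04:05
20 checks, 0 warnings, 0 errors
(20 pass, 0 manual inspection required)
----------------------------------------------------------------------
[C] PASS   completeness:prescription:prescribed_dose  'prescribed_dose' present and as expected
...
[R] PASS   range:nomogram:seeds_ordered  manual seed number 75 within 5 of nomogram value 71.0
----------------------------------------------------------------------
Highlighted variances:
  none
```

The 20 seed-ordering checks are marked `[C]` completeness, `[X]`
consistency and `[R]` range. A 30 cm³ prostate at 145 Gy needs 71 seeds by
the nomogram, so the generated order is 75 (next multiple of 5) and the
nomogram check passes with `d = +4`. Injecting a defect flips the verdict:

```r
inject_defects("demo_chart", list(list(document = "prescription",
                                       field = "prostate_volume",
                                       kind = "inconsistent_value",
                                       magnitude = 3)))
results <- run_process(load_chart("demo_chart"), "seed_ordering")
# -> [X] WARN consistency:prostate_volume  inconsistent prostate_volume:
#    prescription=33 cm3, volume_report=30 cm3   (+ triggered completeness)
```

The monthly audit partitions its 27 item slots into what the digital
documents support (19 auto-checked: signatures present and dated,
documents complete, confirmations ticked) and what they do not (8 manual
to-dos: PNG-embedded plan approvals, the vendor-confirmation screenshot,
binder paperwork, the hot-lab assay logbook):

```r
run_monthly_audit(chart)
#> <audit_report> patient P001: 19/27 slots auto-checked, 8 manual
#>   auto results: 19 pass, 0 warning, 0 error, 0 manual
```

### Command line

```sh
Rscript inst/cli/psichart.R check --chart demo_chart --process seed_ordering --out reports
Rscript inst/cli/psichart.R audit --chart demo_chart --out reports
Rscript inst/cli/psichart.R batch --patients patients.tsv --status active --out reports
Rscript inst/cli/psichart.R generate --n-clean 5 --n-defective 5 --seed 1 --out suite
```

Exit codes: 0 clean, 1 warnings only, 2 errors present, 3 usage/config
failure — suitable for scheduled audit jobs.

## Configuration

Schemas (field lists, labels, expected values, limits), the nomogram and
the audit item list all encode institutional practice and are overridable
via YAML config files; the bundled defaults live in `inst/extdata/`. See
`vignettes/chart-checking.Rmd` for the design rationale and the validation
protocol (clean charts must raise zero flags; injected defects must all be
recalled).
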