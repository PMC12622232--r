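# Alignment tool profiles: one entry per supported many-vs-many protein
# alignment method.  Each command template is expanded with {query},
# {subject}, {out} and {tmpdir}.  All profiles report hits up to
# e-value 1e-5; the conservation filter re-applies that cutoff downstream
# so POCP/POCPu never depend on which tool produced the hit table.
blastp:
  tool: blastp
  dialect: blast
  commands:
    - "blastp -query {query} -subject {subject} -evalue 1e-5 -outfmt 6 -out {out}"
blastpdb:
  tool: blastp
  dialect: blast
  commands:
    - "makeblastdb -in {subject} -dbtype prot -out {tmpdir}/subjectdb"
    - "blastp -query {query} -db {tmpdir}/subjectdb -evalue 1e-5 -outfmt 6 -out {out}"
diamond_fast:
  tool: diamond
  dialect: diamond
  commands:
    - "diamond makedb --in {subject} --db {tmpdir}/subjectdb --quiet"
    - "diamond blastp --fast --query {query} --db {tmpdir}/subjectdb --evalue 1e-5 --outfmt 6 --out {out} --quiet"
diamond_sensitive:
  tool: diamond
  dialect: diamond
  commands:
    - "diamond makedb --in {subject} --db {tmpdir}/subjectdb --quiet"
    - "diamond blastp --sensitive --query {query} --db {tmpdir}/subjectdb --evalue 1e-5 --outfmt 6 --out {out} --quiet"
diamond_verysensitive:
  tool: diamond
  dialect: diamond
  commands:
    - "diamond makedb --in {subject} --db {tmpdir}/subjectdb --quiet"
    - "diamond blastp --very-sensitive --query {query} --db {tmpdir}/subjectdb --evalue 1e-5 --outfmt 6 --out {out} --quiet"
diamond_ultrasensitive:
  tool: diamond
  dialect: diamond
  commands:
    - "diamond makedb --in {subject} --db {tmpdir}/subjectdb --quiet"
    - "diamond blastp --ultra-sensitive --query {query} --db {tmpdir}/subjectdb --evalue 1e-5 --outfmt 6 --out {out} --quiet"
mmseqs2_s1dot0:
  tool: mmseqs
  dialect: mmseqs2
  commands:
    - "mmseqs easy-search {query} {subject} {out} {tmpdir}/mm -s 1.0 -e 1e-5 --format-mode 0"
mmseqs2_s2dot5:
  tool: mmseqs
  dialect: mmseqs2
  commands:
    - "mmseqs easy-search {query} {subject} {out} {tmpdir}/mm -s 2.5 -e 1e-5 --format-mode 0"
mmseqs2_s6dot0:
  tool: mmseqs
  dialect: mmseqs2
  commands:
    - "mmseqs easy-search {query} {subject} {out} {tmpdir}/mm -s 6.0 -e 1e-5 --format-mode 0"
mmseqs2_s7dot5:
  tool: mmseqs
  dialect: mmseqs2
  commands:
    - "mmseqs easy-search {query} {subject} {out} {tmpdir}/mm -s 7.5 -e 1e-5 --format-mode 0"
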