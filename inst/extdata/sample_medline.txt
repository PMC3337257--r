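PMID- 1000001
TI  - Outcomes in tricuspid atresia patients after surgical
      correction in early childhood
AB  - We review long-term outcomes of patients with tricuspid atresia
      undergoing staged palliation. Ventricular function was assessed
      by echocardiography.
TA  - J Thorac Cardiovasc Surg
DP  - 1990 Jan-Feb
MH  - Tricuspid Atresia
MH  - Heart Ventricles/physiology
MH  - *Heart Diseases

PMID- 1000002
TI  - Septal defect closure devices: a registry analysis
AB  - Registry data on transcatheter closure of septal defects.
TA  - Lancet
DP  - 1995
MH  - Heart Septal Defects
MH  - Obsolete Heading Not In Tree

PMID- 1000003
TI  - A title-only record with an unusual date
DP  - 2003 Dec
TA  - BMC Cardiol
MH  - Cardiac Ventricles
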