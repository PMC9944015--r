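department,indication
endodontics,endodontics
orthodontics,orthodontic planning
pedodontics,pedodontics
implantology,implant placement
periodontics,implant placement
oral and maxillofacial surgery,surgical planning and follow-up
radiology,second opinion radiodiagnosis
special care dentistry,medically compromised patient care
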